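test_that("codon alignment threads amino-acid alignment back onto codons", {
  p <- evolve_codon_pair(codon_pair_spec(n_codons = 60, seed = 3))
  aln <- codon_align(p$cds1, p$cds2)
  expect_equal(sum(aln$masked), 0)
  expect_equal(aln$n_codons, 60)
  # one-codon insertion produces exactly one masked gap column
  ins <- paste0(substr(p$cds1, 1, 90), "GCT", substr(p$cds1, 91, nchar(p$cds1)))
  aln2 <- codon_align(p$cds1, ins)
  expect_equal(sum(aln2$masked), 1)
  expect_true(any(aln2$codons1[aln2$masked] == "---"))
  # masked columns equal a direct column scan
  code <- mito_genetic_code()
  direct <- aln2$codons1 == "---" | aln2$codons2 == "---" |
    (!is.na(code[aln2$codons1]) & code[aln2$codons1] == "*") |
    (!is.na(code[aln2$codons2]) & code[aln2$codons2] == "*")
  expect_equal(aln2$masked, unname(direct))
  expect_error(codon_align("ATGA", "ATG"), "in frame")
})

test_that("NG86 estimates: identical, synonymous-only, and toy pathway cases", {
  p <- evolve_codon_pair(codon_pair_spec(n_codons = 30, t = 0, seed = 1))
  est <- kaks_ng86(codon_align(p$cds1, p$cds2))
  expect_equal(est$Ka, 0)
  expect_equal(est$Ks, 0)
  expect_true(est$omega_undefined)
  expect_equal(est$p_fisher, 1)
  # synonymous-only third-position differences: Ka = 0, Ks > 0, omega = 0
  c1 <- c(rep("ATG", 24), "TTA", "GGA", "CGA", "GTA")
  c2 <- c(rep("ATG", 24), "TTG", "GGG", "CGG", "GTG")
  aln <- codon_align(paste(c1, collapse = ""), paste(c2, collapse = ""))
  est2 <- kaks_ng86(aln)
  expect_equal(est2$Ka, 0)
  expect_gt(est2$Ks, 0)
  expect_equal(est2$omega, 0)
  expect_equal(classify_selection(est2$omega), "purifying")
})

test_that("pathway-averaged counts match exhaustive enumeration over a codon panel", {
  panel <- c("TTA", "TTG", "ATA", "AGA")
  for (c1 in panel) for (c2 in panel) {
    oracle <- oracle_path_counts(c1, c2)
    if (is.null(oracle)) next
    got <- anomito:::.codon_path_counts(c1, c2)
    expect_equal(unname(got), unname(oracle), tolerance = 1e-9,
                 info = paste(c1, c2))
  }
  # a classic pathway-ambiguous double difference, via the public surface
  aln <- anomito:::.codon_alignment(c("TTT", "AAA", "ATG", "CCC", "GGG",
                                      "TTA", "CTA", "GAA", "CAA", "AAA"),
                                    c("TTA", "AAA", "ATG", "CCC", "GGG",
                                      "TTA", "CTA", "GAA", "CAA", "AGG"))
  est <- kaks_ng86(aln)
  o1 <- oracle_path_counts("TTT", "TTA")
  o2 <- oracle_path_counts("AAA", "AGG")
  expect_equal(est$S_S, o1[["syn"]] + o2[["syn"]], tolerance = 1e-9)
  expect_equal(est$S_A, o1[["nonsyn"]] + o2[["nonsyn"]], tolerance = 1e-9)
})

test_that("site counts are conserved and estimates are symmetric", {
  set.seed(11)
  for (r in 1:10) {
    p <- evolve_codon_pair(codon_pair_spec(n_codons = 80, t = 0.4,
                                           seed = 200 + r))
    aln <- codon_align(p$cds1, p$cds2)
    est <- kaks_ng86(aln)
    expect_equal(est$L_A + est$L_S, 3 * est$n_codons, tolerance = 1e-6)
    rev_est <- kaks_ng86(codon_align(p$cds2, p$cds1))
    expect_equal(est$Ka, rev_est$Ka, tolerance = 1e-12)
    expect_equal(est$Ks, rev_est$Ks, tolerance = 1e-12)
  }
})

test_that("Fisher exact p-values match full hypergeometric enumeration", {
  est0 <- list(S_A = 0, S_S = 0, L_A = 700, L_S = 300)
  expect_equal(fisher_exact(est0), 1)
  est1 <- list(S_A = 1, S_S = 50, L_A = 100, L_S = 100)
  expect_equal(fisher_exact(est1), oracle_fisher_p(1, 99, 50, 50),
               tolerance = 1e-9)
  set.seed(8)
  for (r in 1:20) {
    la <- sample(50:400, 1); ls <- sample(50:400, 1)
    sa <- sample(0:20, 1); ss <- sample(0:50, 1)
    est <- list(S_A = sa, S_S = ss, L_A = la, L_S = ls)
    expect_equal(fisher_exact(est), oracle_fisher_p(sa, la - sa, ss, ls - ss),
                 tolerance = 1e-9)
  }
  # extreme imbalance stays a positive representable number
  est_big <- list(S_A = 0, S_S = 500, L_A = 3000, L_S = 1000)
  expect_gt(fisher_exact(est_big), 0)
})

test_that("sliding windows tile the alignment in codon units", {
  p <- evolve_codon_pair(codon_pair_spec(n_codons = 156, seed = 21))
  aln <- codon_align(p$cds1, p$cds2)
  ws <- sliding_window(aln)
  expect_equal(nrow(ws), 9)  # floor((156 - 52) / 12) + 1
  expect_equal(ws$window_start_codon, seq(0, 96, by = 12))
  # window = n_codons reproduces the whole-gene estimate
  whole <- sliding_window(aln, window = 156L, step = 12L)
  est <- kaks_ng86(aln)
  expect_equal(nrow(whole), 1)
  expect_equal(whole$Ka, est$Ka)
  expect_equal(whole$Ks, est$Ks)
  expect_error(sliding_window(aln, window = 200L), "shorter")
})

test_that("a divergent block is localized by the maximal-omega window", {
  # conserved background with one 52-codon block evolved at high omega
  bg <- evolve_codon_pair(codon_pair_spec(n_codons = 156, t = 0.05,
                                          omega = 0, seed = 31))
  hot <- evolve_codon_pair(codon_pair_spec(n_codons = 52, t = 0.6,
                                           omega = 2, seed = 32))
  splice <- function(a, b, at) paste0(substr(a, 1, 3 * at),
                                      b, substr(a, 3 * at + 3 * 52 + 1,
                                                nchar(a)))
  c1 <- splice(bg$cds1, hot$cds1, 52)
  c2 <- splice(bg$cds2, hot$cds2, 52)
  ws <- sliding_window(anomito:::.codon_alignment(codon_split(c1),
                                                  codon_split(c2)))
  ratio <- ws$S_A / pmax(ws$S_S, 0.5)
  top <- ws$window_start_codon[which.max(ratio)]
  # block occupies codons 52..104 (0-based); the top window must overlap it
  # by at least a quarter window
  expect_gte(top, 27)
  expect_lte(top, 91)
})

test_that("selection regimes classify by the omega thresholds", {
  expect_equal(classify_selection(0.00287), "purifying")
  expect_equal(classify_selection(1.0), "neutral")
  expect_equal(classify_selection(1.5), "positive")
  expect_equal(classify_selection(0.97), "neutral")
  expect_error(classify_selection(NA_real_), "undefined")
})

test_that("depth-matched pair report produces the 13-gene table", {
  g1 <- generate_genome(genome_spec(seed = 301, accession = "SYNA"))
  rep_ <- depth_pair_report(list(list(g1 = g1$genome, g2 = g1$genome,
                                      depth1 = "0-10 m", depth2 = "0-10 m")))
  expect_equal(nrow(rep_), 13)
  expect_equal(rep_$Ka, rep(0, 13))
  expect_equal(rep_$Ks, rep(0, 13))
  expect_equal(rep_$gene[1], "cox1")
})

test_that("omega is recovered from pairs simulated at known omega", {
  om <- vapply(1:25, function(i) {
    p <- evolve_codon_pair(codon_pair_spec(n_codons = 500, omega = 0.2,
                                           t = 0.3, seed = 400 + i))
    kaks_ng86(codon_align(p$cds1, p$cds2))$omega
  }, numeric(1))
  expect_lt(abs(mean(om) - 0.2), 0.05)
})

test_that("estimated Ks increases with simulated divergence time", {
  ks_at <- function(tt) mean(vapply(1:8, function(i) {
    p <- evolve_codon_pair(codon_pair_spec(n_codons = 200, t = tt,
                                           seed = 500 + i))
    kaks_ng86(codon_align(p$cds1, p$cds2))$Ks
  }, numeric(1)))
  k1 <- ks_at(0.1); k2 <- ks_at(0.3); k3 <- ks_at(0.6)
  expect_lt(k1, k2)
  expect_lt(k2, k3)
})
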