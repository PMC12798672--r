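test_that("tandem repeat finder recovers simple and planted repeats", {
  set.seed(17)
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
  s <- paste0(flank(40), strrep("AT", 6), flank(40))
  tr <- find_tandem_repeats(s)
  hit <- tr[tr$period == 2, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$copy_number, 6.0)
  expect_equal(hit$percent_matches, 100)
  # perfect repeat of known period and copies
  motif <- flank(9)
  s2 <- paste0(flank(30), strrep(motif, 4), flank(30))
  tr2 <- find_tandem_repeats(s2)
  best <- tr2[which.max(tr2$score), ]
  expect_true(best$period == 9 ||
                (9 %% best$period == 0 &&
                   abs(best$period * best$copy_number - 36) <= best$period))
  expect_lt(abs(best$copy_number * best$period / 9 - 4), 0.15 * 4 + 1)
})

test_that("planted 47 bp repeats at 5% mutation are recovered in most backgrounds", {
  ok <- 0L
  for (seed in 1:10) {
    cr <- generate_control_region(cr_spec(seed = 1000 + seed))
    tr <- find_tandem_repeats(cr$sequence)
    if (nrow(tr) == 0) next
    best <- tr[which.max(tr$score), ]
    if (abs(best$period - 47) <= 1 && abs(best$copy_number - 3.6) <= 0.3)
      ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("SSR scan equals an independent regex oracle", {
  set.seed(23)
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
  s <- paste0(flank(20), strrep("AT", 8), flank(10))
  hit <- find_ssrs(s)
  expect_equal(hit$unit, "AT")
  expect_equal(hit$copies, 8L)
  s2 <- paste0(flank(12), strrep("A", 15), flank(12))
  hit2 <- find_ssrs(s2)
  expect_equal(hit2$unit, "A")
  expect_equal(hit2$copies, 15L)
  # random sequence, full comparison against the oracle
  for (r in 1:5) {
    rs <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE,
                       prob = c(.4, .1, .1, .4)), collapse = "")
    rs <- paste0(rs, strrep("TA", 7), strrep("C", 13))
    got <- find_ssrs(rs)
    want <- oracle_ssrs(rs)
    expect_equal(got$start, want$start)
    expect_equal(got$unit, want$unit)
    expect_equal(got$copies, want$copies)
  }
})

test_that("inverted repeats are found with correct arms and loops", {
  set.seed(31)
  arm <- paste(sample(c("A", "C", "G", "T"), 15, TRUE), collapse = "")
  s <- paste0(strrep("T", 12), arm, "AAAA", revcomp(arm), strrep("G", 12))
  ir <- find_inverted_repeats(s)
  expect_equal(nrow(ir), 1)
  expect_equal(ir$arm_length, 15)
  expect_equal(ir$loop_length, 4)
  expect_equal(ir$start1, 13)
  expect_equal(ir$end2, 12 + 15 + 4 + 15)
  # no qualifying arm -> empty (AC repeats have no complementary partner)
  expect_equal(nrow(find_inverted_repeats(strrep("AC", 40))), 0)
  # two planted hairpins both recovered at the right coordinates
  cr <- generate_control_region(cr_spec(hairpin_stems = list(c(12L, 5L),
                                                             c(12L, 5L)),
                                        seed = 77))
  ir2 <- find_inverted_repeats(cr$sequence)
  hp <- cr$truth$hairpins
  expect_equal(nrow(hp), 2)
  for (k in seq_len(nrow(hp))) {
    match_k <- any(abs(ir2$start1 - hp$start[k]) <= 2 &
                     abs(ir2$end2 - hp$end[k]) <= 2)
    expect_true(match_k, info = paste("hairpin", k))
  }
})

test_that("motif blocks are annotated by their defining patterns", {
  m1 <- annotate_motifs("AAATTTTTTTAAA", hairpins = FALSE)
  expect_equal(m1$kind, "polyT")
  m2 <- annotate_motifs("CCTATAATAACC", hairpins = FALSE)
  expect_equal(m2$kind, "TAA_block")
  m3 <- annotate_motifs("CCGAGAGGACC", hairpins = FALSE)
  expect_equal(m3$kind, "GA_block")
  # GA blocks are subtyped relative to the main tandem repeat
  set.seed(3)
  cr <- generate_control_region(cr_spec(seed = 55))
  mo <- annotate_motifs(cr$sequence)
  ga <- mo[mo$kind == "GA_block", ]
  expect_gt(nrow(ga), 0)
  expect_true(all(ga$subtype %in% c("5prime", "3prime", "none")))
})

test_that("MFE folding matches exhaustive enumeration on short sequences", {
  set.seed(1234)
  worst <- 0
  for (r in 1:60) {
    n <- sample(10:30, 1)
    s <- paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
    d <- abs(fold_mfe(s, max_suboptimals = 0)$delta_g -
               fold_enumerate(s)$delta_g)
    worst <- max(worst, d)
  }
  expect_lt(worst, 1e-6)
  # fixed example
  expect_equal(fold_mfe("GGGGAAAACCCC", max_suboptimals = 0)$delta_g,
               fold_enumerate("GGGGAAAACCCC")$delta_g, tolerance = 1e-9)
})

test_that("folding contracts: open chain, suboptimal band, validity", {
  f <- fold_mfe(strrep("A", 50))
  expect_equal(f$delta_g, 0)
  expect_equal(f$structure, strrep(".", 50))
  cr <- generate_control_region(cr_spec(length = 300L, seed = 12))
  f2 <- fold_mfe(cr$sequence, max_suboptimals = 5)
  expect_lt(f2$delta_g, 0)
  expect_lte(nrow(f2$suboptimals), 5)
  if (nrow(f2$suboptimals) > 0)
    expect_true(all(f2$suboptimals$delta_g >= f2$delta_g - 1e-9))
  # MFE structure energy is reproduced by the standalone evaluator
  pl <- which(f2$pairing > seq_along(f2$pairing))
  pairs <- cbind(pl, f2$pairing[pl])
  expect_equal(structure_energy(cr$sequence, pairs), f2$delta_g,
               tolerance = 1e-6)
  expect_error(fold_mfe(paste0(strrep("N", 30), strrep("A", 30))),
               "ambiguity")
  expect_error(fold_mfe("ACGT"), "length")
})

test_that("dG is invariant under complementation with reversal (Watson-Crick subset)", {
  # strand symmetry holds exactly for the Watson-Crick pair set; GU wobble
  # pairs map to unpairable A:C under complementation and break it
  set.seed(88)
  for (r in 1:15) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(20:60, 1), TRUE),
               collapse = "")
    f1 <- fold_mfe(s, max_suboptimals = 0, allow_wobble = FALSE)
    f2 <- fold_mfe(revcomp(s), max_suboptimals = 0, allow_wobble = FALSE)
    expect_equal(f1$delta_g, f2$delta_g, tolerance = 1e-6)
  }
})

test_that("appending a perfect GC hairpin never raises the MFE", {
  set.seed(55)
  hp <- paste0(strrep("G", 10), "AAAA", strrep("C", 10))
  for (r in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    expect_lte(fold_mfe(paste0(s, hp), max_suboptimals = 0)$delta_g,
               fold_mfe(s, max_suboptimals = 0)$delta_g + 1e-9)
  }
})

test_that("tRNA folds classify as cloverleaf or atypical", {
  v <- classify_trna_structure(synthetic_trna())
  expect_equal(as.character(v), "cloverleaf")
  expect_equal(attr(v, "detail")$n_hairpins, 3)
  expect_gte(attr(v, "detail")$acceptor, 4)
  v2 <- classify_trna_structure(synthetic_trna(drop_d_arm = TRUE))
  expect_equal(as.character(v2), "atypical")
  v3 <- classify_trna_structure(strrep("A", 40))
  expect_equal(as.character(v3), "atypical")
  expect_error(classify_trna_structure(strrep("A", 30)), "40-120")
})

test_that("vienna output carries structure and energy per record", {
  f <- fold_mfe("GGGGAAAACCCC", max_suboptimals = 0)
  p <- tempfile(fileext = ".vienna")
  write_vienna(list(rec1 = f), "GGGGAAAACCCC", p)
  lines <- readLines(p)
  expect_match(lines[1], "rec1 dG = ")
  expect_equal(lines[2], "GGGGAAAACCCC")
  expect_equal(nchar(lines[3]), 12)
})
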