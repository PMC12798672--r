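test_that("base composition and skews match direct counting", {
  p <- composition("AATT")
  expect_equal(unname(p$pct), c(50, 0, 0, 50))  # A C G T
  expect_equal(p$at_skew, 0)
  p2 <- composition("ACGT")
  expect_equal(unname(p2$pct), rep(25, 4))
  expect_equal(p2$at_skew, 0)
  expect_equal(p2$gc_skew, 0)
  # published genome-scale composition reproduces the published AT skew
  s <- paste0(strrep("A", 317), strrep("T", 418), strrep("C", 98),
              strrep("G", 167))
  expect_equal(round_half_away(composition(s)$at_skew, 3), -0.137)
  # N excluded from denominators
  expect_equal(composition("AANN")$pct[["A"]], 100)
  expect_error(composition("ACGR"), "ambiguity")
  expect_error(composition(""), "empty")
})

test_that("skew helpers reproduce published values and basic symmetries", {
  expect_equal(round_half_away(at_skew(31.7, 41.8), 3), -0.137)
  expect_equal(round_half_away(at_skew(29.2, 38.5), 3), -0.137)
  expect_equal(round_half_away(gc_skew(16.6, 14.1), 3), 0.081)
  expect_equal(round_half_away(gc_skew(17.8, 13.3), 3), 0.145)
  for (x in c(1, 17.3, 50)) {
    expect_equal(at_skew(x, x), 0)
    expect_equal(gc_skew(x, x), 0)
  }
  expect_error(at_skew(0, 0), "undefined")
  expect_error(gc_skew(0, 0), "undefined")
})

test_that("skews computed from counts equal skews from unrounded percentages", {
  set.seed(101)
  for (r in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE,
                      prob = runif(4, 0.05, 0.5)), collapse = "")
    p <- composition(s)
    expect_equal(p$at_skew, at_skew(p$pct[["A"]], p$pct[["T"]]),
                 tolerance = 1e-12)
    expect_equal(p$gc_skew, gc_skew(p$pct[["G"]], p$pct[["C"]]),
                 tolerance = 1e-12)
    # skew(s) = -skew(revcomp(s))
    q <- composition(revcomp(s))
    expect_equal(q$at_skew, -p$at_skew, tolerance = 1e-12)
    expect_equal(q$gc_skew, -p$gc_skew, tolerance = 1e-12)
  }
})

test_that("composition of a concatenation is the count-weighted merge of parts", {
  set.seed(7)
  a <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  b <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  merged <- composition(paste0(a, b))
  expect_equal(merged$counts,
               composition(a)$counts + composition(b)$counts)
})

test_that("the mixed skew report emits heavy-strand AT with light-strand GC skew", {
  s <- paste0(strrep("A", 317), strrep("T", 418), strrep("C", 98),
              strrep("G", 167))
  feats <- data.frame(name = "cox1", start = 1L, end = 30L, strand = "+",
                      kind = "PCG", wraps = FALSE)
  g <- suppressWarnings(mito_genome("SKEW1", s, feats))
  rep_ <- skew_report(g)
  expect_equal(rep_$strand_label, c("heavy", "light", "mixed"))
  mixed <- rep_[rep_$strand_label == "mixed", ]
  light <- rep_[rep_$strand_label == "light", ]
  heavy <- rep_[rep_$strand_label == "heavy", ]
  expect_equal(mixed$at_skew, heavy$at_skew)
  expect_equal(mixed$gc_skew, light$gc_skew)
  expect_equal(heavy$at_skew, -0.137)
})

test_that("codon usage counts match a brute-force tally and RSCU averages to 1", {
  cu <- codon_usage(list("ATGATG"))
  expect_equal(cu$count[cu$codon == "ATG"], 2L)
  expect_equal(cu$per_thousand[cu$codon == "ATG"], 1000)
  cu2 <- codon_usage(list("TTTTTC"))
  expect_equal(cu2$rscu[cu2$codon %in% c("TTT", "TTC")], c(1, 1))
  # random codons vs independent tally
  set.seed(33)
  cods <- sample(names(mito_genetic_code()), 100, replace = TRUE)
  cu3 <- codon_usage(list(paste(cods, collapse = "")))
  tally <- table(factor(cods, levels = cu3$codon))
  expect_equal(cu3$count, as.integer(tally))
  # RSCU means 1 within families that are present
  code <- mito_genetic_code()
  for (aa in unique(code)) {
    fam <- cu3[cu3$aa == aa, ]
    if (sum(fam$count) > 0) expect_equal(mean(fam$rscu), 1, tolerance = 1e-12)
  }
  expect_error(codon_usage(list("ATGA")), "frame error")
})
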