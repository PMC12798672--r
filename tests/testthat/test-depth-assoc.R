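test_that("depth categories bin by midpoint with terrestrial override", {
  expect_equal(assign_depth_category(0, 30), "Intertidal")     # midpoint 15
  expect_equal(assign_depth_category(1000, 2000), "Deep sea")  # midpoint 1500
  expect_equal(assign_depth_category(30, 30), "Shallow")       # boundary
  expect_equal(assign_depth_category(100, 500), "Upper bathyal")
  expect_equal(assign_depth_category(5, 10, terrestrial = TRUE), "Terrestrial")
  expect_error(assign_depth_category(-1, 5), ">= 0")
  # total and deterministic over [0, 10000]
  cats <- vapply(seq(0, 10000, by = 97), function(d)
    assign_depth_category(d, d), character(1))
  expect_true(all(cats %in% c("Intertidal", "Shallow", "Upper bathyal",
                              "Deep sea")))
  expect_identical(cats, vapply(seq(0, 10000, by = 97), function(d)
    assign_depth_category(d, d), character(1)))
})

test_that("strictly co-monotone records give |rho| = 1", {
  rec <- data.frame(family = "Fam", dg_mid = -c(10, 20, 30, 40, 50),
                    depth_mid = c(5, 50, 500, 1000, 2000),
                    depth_max = c(5, 50, 500, 1000, 2000),
                    terrestrial = FALSE, vent = FALSE)
  tr <- dg_depth_trend(rec, n_perm = 500)
  expect_equal(tr$spearman_rho, -1)
  expect_equal(tr$direction, "decreasing")
  rec$dg_mid <- -rec$dg_mid
  tr2 <- dg_depth_trend(rec, n_perm = 500)
  expect_equal(tr2$spearman_rho, 1)
  expect_equal(tr2$direction, "increasing")
})

test_that("packaged comparative table reproduces the family-wise trend directions", {
  hab <- habitat_table()
  expect_equal(nrow(hab), 49)
  tr <- suppressMessages(dg_depth_trend(hab, min_n = 3, n_perm = 2000))
  litho <- tr[tr$family == "Lithodidae", ]
  # hand-computed Spearman on the six printed midpoints: 1 - 6*2/210
  expect_equal(litho$spearman_rho, 0.942857142857, tolerance = 1e-9)
  expect_equal(litho$direction, "increasing")
  expect_lt(tr$spearman_rho[tr$family == "Paguridae"], 0)
  expect_equal(tr$n[tr$family == "Paguridae"], 8)  # Too-compact row excluded
  expect_lt(tr$spearman_rho[tr$family == "Diogenidae"], 0)
  # vent taxa (Munidopsidae) are excluded and counted
  expect_false("Munidopsidae" %in% tr$family)
})

test_that("trends are invariant to record order and monotone depth transforms", {
  hab <- habitat_table()
  tr1 <- suppressMessages(dg_depth_trend(hab, min_n = 3, n_perm = 200))
  hab2 <- hab[rev(seq_len(nrow(hab))), ]
  tr2 <- suppressMessages(dg_depth_trend(hab2, min_n = 3, n_perm = 200))
  m <- match(tr1$family, tr2$family)
  expect_equal(tr1$spearman_rho, tr2$spearman_rho[m])
  hab3 <- hab
  hab3$depth_mid <- log1p(hab3$depth_mid)   # strictly monotone transform
  tr3 <- suppressMessages(dg_depth_trend(hab3, min_n = 3, n_perm = 200))
  expect_equal(tr1$spearman_rho, tr3$spearman_rho[match(tr1$family,
                                                        tr3$family)])
})

test_that("permutation p-values are reproducible under a fixed seed", {
  hab <- habitat_table()
  tr1 <- suppressMessages(dg_depth_trend(hab, seed = 7L))
  tr2 <- suppressMessages(dg_depth_trend(hab, seed = 7L))
  expect_identical(tr1$p_perm, tr2$p_perm)
})

test_that("families below the minimum size are skipped with a notice", {
  hab <- habitat_table()
  expect_message(tr <- dg_depth_trend(hab, min_n = 4), "skipped")
  expect_false("Diogenidae" %in% tr$family)  # only 3 usable rows
})

test_that("carcinization contrast separates modal trend directions", {
  toy <- data.frame(
    family = c("Lithodidae", "Porcellanidae", "FamA", "FamB"),
    n = 5, spearman_rho = c(0.9, 0.8, -0.9, -0.7),
    direction = c("increasing", "increasing", "decreasing", "decreasing"),
    p_perm = 0.05, vent_excluded = 0, stringsAsFactors = FALSE)
  ct <- carcinization_contrast(toy)
  expect_true(ct$contrast)
  expect_equal(ct$summary$concordance, c(1, 1))
  # packaged table: Lithodidae direction differs from Paguridae/Diogenidae
  tr <- suppressMessages(dg_depth_trend(habitat_table(), min_n = 3,
                                        n_perm = 200))
  ct2 <- carcinization_contrast(tr)
  bf <- ct2$by_family
  expect_equal(bf$direction[bf$family == "Lithodidae"], "increasing")
  expect_equal(bf$direction[bf$family == "Paguridae"], "decreasing")
  expect_equal(bf$direction[bf$family == "Diogenidae"], "decreasing")
  # degenerate single-family input
  ct3 <- carcinization_contrast(toy[1, ])
  expect_true(is.na(ct3$contrast))
  expect_equal(nrow(ct3$by_family), 1)
})
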