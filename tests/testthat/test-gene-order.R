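test_that("canonicalization fixes rotation and reflection", {
  expect_equal(canonicalize(c("+trnW", "+cox1", "-trnY")),
               c("+cox1", "-trnY", "+trnW"))
  expect_equal(canonicalize(c("-cox1", "+trnY", "-trnW")),
               c("+cox1", "+trnW", "-trnY"))
  # idempotence
  gp <- ground_pattern("canonical37")
  expect_equal(canonicalize(gp)$order, gp$order)
  expect_error(canonicalize(c("+trnA", "+trnB")), "lacks cox1")
  # brute force over all rotations/reflections on random orders
  set.seed(5)
  for (r in 1:50) {
    ord <- random_signed_order(sample(4:12, 1))
    expect_equal(canonicalize(ord), brute_canonical(ord))
  }
})

test_that("arrangement typing partitions by exact canonical equality", {
  o <- function(acc, v) gene_order(v, accession = acc)
  base <- c("+cox1", "+trnA", "-trnB", "+trnC")
  alt <- c("+cox1", "-trnB", "+trnA", "+trnC")
  tp <- partition_types(list(o("a1", base), o("a2", base),
                             o("a3", c("+trnA", "-trnB", "+trnC", "+cox1")),
                             o("a4", alt)))
  expect_length(tp, 2)
  expect_setequal(tp[[1]]$members, c("a1", "a2", "a3"))  # rotation = same type
  expect_equal(tp[[2]]$members, "a4")
  # invariance under input permutation (membership as sets)
  tp2 <- partition_types(list(o("a4", alt), o("a3", base), o("a1", base),
                              o("a2", base)))
  sets1 <- lapply(tp, function(t) sort(t$members))
  sets2 <- lapply(tp2, function(t) sort(t$members))
  expect_setequal(vapply(sets1, paste, "", collapse = ","),
                  vapply(sets2, paste, "", collapse = ","))
})

test_that("generator-planted arrangement classes are recovered by typing", {
  plans <- list(list(),
                list(list(type = "transposition", gene = "trnI",
                          after = "trnM")),
                list(list(type = "inversion", genes = "trnW")))
  orders <- list()
  for (i in 1:6) {
    g <- generate_genome(genome_spec(
      rearrangements = plans[[((i - 1) %% 3) + 1]],
      accession = sprintf("SYN%03d", i), seed = 100 + i))
    orders[[i]] <- gene_order_from_genome(g$genome)
  }
  expect_length(partition_types(orders), 3)
})

test_that("diff against the reference identifies translocations and inversions", {
  gp <- ground_pattern("canonical37")
  expect_s3_class(diff_vs_reference(gp, gp), "RearrangementDiff")
  d0 <- diff_vs_reference(gp, gp)
  expect_length(d0$translocated, 0)
  expect_length(d0$inverted, 0)
  # swap the adjacent trnI / trnM block markers
  ord <- gp$order
  i <- which(ord == "+trnI"); m <- which(ord == "+trnM")
  ord2 <- ord; ord2[i] <- "+trnM"; ord2[m] <- "+trnI"
  d <- diff_vs_reference(gene_order(ord2), gp)
  expect_setequal(d$translocated, c("trnI", "trnM"))
  expect_length(d$inverted, 0)
  # single-gene strand flip within a conserved neighbourhood
  ord3 <- ord; ord3[ord3 == "+trnT"] <- "-trnT"
  d3 <- diff_vs_reference(gene_order(ord3), gp)
  expect_equal(d3$inverted, "trnT")
  expect_length(d3$translocated, 0)
  # genes absent from the reference are ignored
  ord4 <- append(ord, "+gX", after = 3)
  d4 <- diff_vs_reference(gene_order(ord4), gp)
  expect_length(d4$translocated, 0)
})

test_that("diff of an order against itself is empty for random orders", {
  set.seed(42)
  for (r in 1:200) {
    ord <- random_signed_order(sample(5:15, 1))
    d <- diff_vs_reference(gene_order(ord), gene_order(ord))
    expect_length(d$translocated, 0)
    expect_length(d$inverted, 0)
  }
})

test_that("breakpoint distance: identity, symmetry, adjacent transposition", {
  o1 <- paste0("+", c("cox1", letters[1:7]))
  expect_equal(breakpoint_distance(o1, o1), 0L)
  # move one gene to the adjacent slot in an 8-gene circle
  o2 <- paste0("+", c("cox1", "a", "c", "b", "d", "e", "f", "g"))
  expect_equal(breakpoint_distance(o1, o2), 3L)
  expect_equal(breakpoint_distance(o2, o1), 3L)
  expect_equal(breakpoint_distance(o1, o2), brute_breakpoints(o1, o2))
})

test_that("breakpoint distance and typing agree with brute-force enumeration on random permutations", {
  set.seed(99)
  for (r in 1:200) {
    n <- sample(4:15, 1)
    genes <- c("cox1", paste0("g", seq_len(n - 1)))
    o1 <- paste0(sample(c("+", "-"), n, TRUE), sample(genes))
    o2 <- paste0(sample(c("+", "-"), n, TRUE), sample(genes))
    expect_equal(breakpoint_distance(o1, o2), brute_breakpoints(o1, o2))
    expect_equal(breakpoint_distance(o2, o1), brute_breakpoints(o2, o1))
    # identity iff equal canonical orders
    eq <- identical(canonicalize(o1), canonicalize(o2))
    expect_equal(breakpoint_distance(o1, o2) == 0L, eq)
  }
})

test_that("both reference ground patterns are canonical and well-formed", {
  gp37 <- ground_pattern("canonical37")
  expect_length(gp37$order, 37)
  expect_setequal(sub("^[+-]", "", gp37$order), gene_vocabulary(FALSE))
  expect_equal(gp37$order[1], "+cox1")
  gpp <- ground_pattern("paper")
  expect_length(gpp$order, 32)
  expect_equal(gpp$order[1], "+cox1")
  # the printed anchor string omits five genes
  expect_setequal(setdiff(gene_vocabulary(FALSE),
                          sub("^[+-]", "", gpp$order)),
                  c("trnG", "trnA", "trnV", "rrnL", "rrnS"))
})
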