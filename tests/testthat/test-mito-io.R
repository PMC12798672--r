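test_that("GenBank parsing maps heterogeneous labels onto the canonical vocabulary", {
  g <- read_genbank(tiny_genbank())
  expect_s3_class(g, "MitoGenome")
  expect_equal(g$accession, "TEST0001")
  expect_equal(g$taxon, "Testia minima")
  expect_setequal(g$features$name, c("cox1", "trnL2", "rrnL"))
  expect_equal(g$features$kind[g$features$name == "trnL2"], "tRNA")
  expect_equal(g$features$strand[g$features$name == "rrnL"], "-")
  expect_true(g$circular)
  expect_match(g$sequence, "^[ACGTN]+$")
})

test_that("records without mappable features raise an annotation error", {
  expect_error(read_genbank(empty_genbank()), "annotation error.*EMPTY001")
  notgb <- tempfile()
  writeLines("this is not a genbank file", notgb)
  expect_error(read_genbank(notgb), "not a GenBank")
})

test_that("FASTA reading normalizes case and alphabet", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">one", "ACGT", ">two", "acgu"), f)
  s <- read_fasta(f)
  expect_equal(unname(s), c("ACGT", "ACGT"))
  expect_equal(names(s), c("one", "two"))
  f1 <- tempfile(fileext = ".fa")
  writeLines(c(">solo", "ACGT"), f1)
  expect_equal(unname(read_fasta(f1)), "ACGT")
  f2 <- tempfile(fileext = ".fa")
  file.create(f2)
  expect_error(read_fasta(f2), "empty|format")
})

test_that("canonical name mapping is idempotent and total over the synonym table", {
  syn <- gene_synonyms()
  mapped <- canonical_gene_name(syn$synonym)
  expect_false(any(is.na(mapped)))
  expect_equal(mapped, syn$canonical)
  # idempotence over the whole vocabulary
  expect_equal(canonical_gene_name(gene_vocabulary()), gene_vocabulary())
  # anticodon disambiguation of the duplicated leucine/serine tRNAs
  expect_equal(canonical_gene_name(c("trnL(taa)", "trnL(tag)", "tRNA-Ser-UCU",
                                     "trnS(tga)")),
               c("trnL2", "trnL1", "trnS1", "trnS2"))
  # bare ambiguous leucine stays unmapped
  expect_true(is.na(canonical_gene_name("tRNA-Leu")))
})

test_that("the control region is the longest unannotated circular gap", {
  g <- gapped_genome(gap = 800L, seed = 11L)
  reg <- locate_control_region(g$genome)
  expect_equal(reg$status, "ok")
  # the located gap must contain the planted CR and be the longest gap
  expect_lte(reg$start, g$truth$cr_start)
  expect_gte(reg$end, g$truth$cr_end)
  expect_equal(reg$length, brute_gaps(g$genome))
  # flanks: CR was planted right after rrnS
  expect_equal(reg$flank5, "rrnS")
})

test_that("control-region location agrees with a brute-force gap scan on random genomes", {
  for (seed in 1:12) {
    g <- generate_genome(genome_spec(
      cr_spec_ = cr_spec(length = sample(300:1500, 1), seed = seed + 50L),
      seed = seed))
    reg <- locate_control_region(g$genome)
    expect_equal(reg$length, brute_gaps(g$genome), info = paste("seed", seed))
  }
})

test_that("an explicit CR annotation takes precedence and compact genomes are flagged", {
  g <- generate_genome(genome_spec(annotate_cr = TRUE, seed = 4L))
  reg <- locate_control_region(g$genome)
  expect_equal(reg$status, "ok")
  expect_equal(reg$start, g$truth$cr_start)
  expect_equal(reg$end, g$truth$cr_end)
  # genome whose largest gap is under the threshold
  feats <- data.frame(name = c("cox1", "trnA"), start = c(1L, 61L),
                      end = c(30L, 120L), strand = "+",
                      kind = c("PCG", "tRNA"), wraps = FALSE)
  gsm <- mito_genome("SMALL", strrep("ACGT", 40), feats)
  expect_equal(locate_control_region(gsm)$status, "too compact")
})

test_that("CDS extraction trims frame and stops, handles strand", {
  feats <- data.frame(
    name = c("cox1", "cox2", "nad3"),
    start = c(1L, 22L, 43L), end = c(9L, 30L, 52L),
    strand = c("+", "-", "+"), kind = "PCG", wraps = FALSE)
  seq <- paste0("ATGAAATAA", "AGC", "TTATTTCAT", "AGCTGATCAT", "GGGG")
  # positions: cox1 1..9 (+); cox2 22..30 (-); nad3 43..52 (10 bp)
  seq <- paste0("ATGAAATAA",            # 1..9
                "AGCAGCAGCAGC",         # 10..21 filler
                "TTACATCAT",            # 22..30 (- strand: ATGATGTAA)
                "AGCTGATCAGCT",         # 31..42 filler
                "ATGCCCTAAG")           # 43..52 (10 bp, 3' trim)
  g <- mito_genome("CDS1", seq, feats)
  expect_equal(extract_cds(g, "cox1"), "ATGAAA")
  expect_equal(extract_cds(g, "cox2"), "ATGATG")
  expect_equal(extract_cds(g, "nad3"), "ATGCCC")  # 9 bp after trim + stop
  expect_error(extract_cds(g, "cob"), "not annotated")
  # internal stop warns but returns
  feats2 <- data.frame(name = "nad1", start = 1L, end = 9L, strand = "+",
                       kind = "PCG", wraps = FALSE)
  g2 <- mito_genome("CDS2", paste0("TAAAAATTT", "GGG"), feats2)
  expect_warning(out <- extract_cds(g2, "nad1"), "internal stop")
  expect_equal(out, "TAAAAATTT")
})

test_that("gene-order TSV round-trips the identical GeneOrder", {
  g <- generate_genome(genome_spec(seed = 9L))
  ord <- gene_order_from_genome(g$genome)
  p <- tempfile(fileext = ".tsv")
  write_gene_order_tables(list(ord), order_path = p)
  back <- read_gene_order_table(p)[[1]]
  expect_equal(canonicalize(back)$order, canonicalize(ord)$order)
  # feature table columns are fixed
  pf <- tempfile(fileext = ".tsv")
  write_feature_table(g$genome, pf)
  expect_equal(names(read.delim(pf)),
               c("accession", "gene", "start", "end", "strand", "kind"))
})

test_that("wraparound features are parsed and sliced correctly", {
  L <- 120L
  seqs <- strrep("ACGT", 30)
  feats <- data.frame(name = c("cox1", "trnA"), start = c(111L, 20L),
                      end = c(10L, 80L), strand = "+",
                      kind = c("PCG", "tRNA"), wraps = c(TRUE, FALSE))
  g <- mito_genome("WRAP1", seqs, feats)
  p <- tempfile(fileext = ".gb")
  write_genbank(g, p)
  g2 <- read_genbank(p)
  i <- which(g2$features$name == "cox1")
  expect_true(g2$features$wraps[i])
  expect_equal(g2$features$start[i], 111L)
  expect_equal(g2$features$end[i], 10L)
})
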