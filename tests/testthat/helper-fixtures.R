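# Small text fixtures built in code.

# hand-written GenBank record: 3 features incl. an anticodon-tagged tRNA
tiny_genbank <- function(path = tempfile(fileext = ".gb")) {
  seq <- paste0(
    "ATGAAACCCGGGTTTACCTAA",              # 1..21  CDS cox1 (+)
    "ACGTACGTACGTACGTACGTACGTACGTACGT",   # 22..53 tRNA trnL(taa) (+)
    strrep("AT", 40),                     # 54..133 gap
    "GGGTTTAAACCC")                       # 134..145 rRNA 16S (-)
  lines <- c(
    sprintf("LOCUS       TEST0001%17d bp    DNA     circular INV 01-JAN-2026",
            nchar(seq)),
    "DEFINITION  Testia minima mitochondrion.",
    "  ORGANISM  Testia minima",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(seq)),
    '                     /organism="Testia minima"',
    "     CDS             1..21",
    '                     /gene="COI"',
    "     tRNA            22..53",
    '                     /product="trnL(taa)"',
    "     rRNA            complement(134..145)",
    '                     /product="16S ribosomal RNA"',
    "ORIGIN",
    paste0("        1 ", tolower(substr(seq, 1, 60))),
    paste0("       61 ", tolower(substr(seq, 61, 120))),
    paste0("      121 ", tolower(substr(seq, 121, nchar(seq)))),
    "//")
  writeLines(lines, path)
  path
}

empty_genbank <- function(path = tempfile(fileext = ".gb")) {
  writeLines(c(
    "LOCUS       EMPTY001               24 bp    DNA     circular INV 01-JAN-2026",
    "DEFINITION  nothing.",
    "FEATURES             Location/Qualifiers",
    "     source          1..24",
    "ORIGIN",
    "        1 acgtacgtacgtacgtacgtacgt",
    "//"), path)
  path
}

# a genome with an explicitly placed gap of known size for the CR locator
gapped_genome <- function(gap = 800L, seed = 1L) {
  sp <- genome_spec(cr_spec_ = cr_spec(length = gap, seed = seed + 7L),
                    seed = seed)
  generate_genome(sp)
}
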