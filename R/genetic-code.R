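## Invertebrate mitochondrial genetic code (NCBI translation table 5) and
## small sequence utilities shared across modules.

.codegrid <- new.env(parent = emptyenv())

#' Invertebrate mitochondrial genetic code
#'
#' Named character vector mapping the 64 codons (DNA alphabet) to one-letter
#' amino acids, with `"*"` for the stop codons (TAA, TAG under table 5).
#'
#' @return named character vector of length 64.
#' @export
mito_genetic_code <- function() {
  if (is.null(.codegrid$code5)) {
    code <- Biostrings::getGeneticCode("5")
    names(code) <- chartr("U", "T", names(code))
    .codegrid$code5 <- code
  }
  .codegrid$code5
}

#' Translate an in-frame DNA sequence with the invertebrate mito code
#'
#' @param dna DNA string, length a multiple of 3.
#' @param allow_partial if `TRUE`, a trailing partial codon is dropped.
#' @return amino-acid string (stops as `*`, codons with N/other as `X`).
#' @export
translate_mito <- function(dna, allow_partial = FALSE) {
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n %% 3 != 0) {
    if (!allow_partial)
      stop("sequence length ", n, " is not a multiple of 3", call. = FALSE)
    dna <- substr(dna, 1L, n - n %% 3)
  }
  cods <- codon_split(dna)
  aa <- mito_genetic_code()[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Split an in-frame DNA string into codons
#' @param dna DNA string (length multiple of 3).
#' @return character vector of codons.
#' @export
codon_split <- function(dna) {
  n <- nchar(dna)
  if (n == 0L) return(character(0))
  substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Reverse complement of a DNA string
#' @param dna DNA string over `{A,C,G,T,N}` (case-insensitive).
#' @return reverse-complemented uppercase string.
#' @export
revcomp <- function(dna) {
  vapply(dna, function(s) {
    s <- toupper(s)
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

## Sense (non-stop) codons under table 5
sense_codons <- function() {
  code <- mito_genetic_code()
  names(code)[code != "*"]
}

#' Round half away from zero
#'
#' Report rounding convention used for printed percentages and skews
#' (base R's `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
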