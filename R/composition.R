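## composition_stats: base composition, AT/GC skew (Perna & Kocher), codon
## usage. Skews: AT skew = (A - T) / (A + T), GC skew = (G - C) / (G + C),
## computed per strand; percentages exclude N from the denominator.

#' Base composition and skews of a DNA sequence
#'
#' @param seq DNA string; `N` is allowed and excluded from denominators,
#'   other ambiguity codes are rejected.
#' @param strand_label `"heavy"` or `"light"`, carried into the profile.
#' @return list of class `CompositionProfile`: per-base `counts`, unrounded
#'   `pct`, `at_content`, `gc_content`, `at_skew`, `gc_skew` (all unrounded;
#'   use [format_composition()] for report rounding), `strand_label`.
#' @export
composition <- function(seq, strand_label = "heavy") {
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("empty sequence", call. = FALSE)
  if (grepl("[^ACGTN]", seq))
    stop("ambiguity codes other than N are not supported", call. = FALSE)
  counts <- vapply(c("A", "C", "G", "T"), function(b)
    lengths(regmatches(seq, gregexpr(b, seq, fixed = TRUE))), numeric(1))
  tot <- sum(counts)
  if (tot == 0L) stop("sequence contains only N", call. = FALSE)
  pct <- 100 * counts / tot
  a <- counts[["A"]]; t <- counts[["T"]]
  g <- counts[["G"]]; c <- counts[["C"]]
  structure(list(
    counts = counts, pct = pct,
    at_content = pct[["A"]] + pct[["T"]],
    gc_content = pct[["G"]] + pct[["C"]],
    at_skew = if (a + t > 0) (a - t) / (a + t) else NA_real_,
    gc_skew = if (g + c > 0) (g - c) / (g + c) else NA_real_,
    strand_label = strand_label), class = "CompositionProfile")
}

#' @export
print.CompositionProfile <- function(x, ...) {
  p <- round_half_away(x$pct, 1)
  cat(sprintf("CompositionProfile (%s strand): A=%.1f%% C=%.1f%% G=%.1f%% T=%.1f%%\n",
              x$strand_label, p[["A"]], p[["C"]], p[["G"]], p[["T"]]))
  cat(sprintf("  AT=%.1f%%  AT skew=%.3f  GC skew=%.3f\n",
              round_half_away(x$at_content, 1),
              round_half_away(x$at_skew, 3), round_half_away(x$gc_skew, 3)))
  invisible(x)
}

#' AT skew from A and T percentages
#'
#' Strand-asymmetry statistic of Perna & Kocher: `(A - T) / (A + T)`.
#'
#' @param a_pct,t_pct percentages (or counts; only the ratio matters).
#' @return skew in `[-1, 1]`, unrounded.
#' @export
at_skew <- function(a_pct, t_pct) {
  if (a_pct + t_pct <= 0) stop("undefined skew: A + T = 0", call. = FALSE)
  (a_pct - t_pct) / (a_pct + t_pct)
}

#' GC skew from G and C percentages
#'
#' `(G - C) / (G + C)`, following Perna & Kocher.
#'
#' @param g_pct,c_pct percentages (or counts).
#' @return skew in `[-1, 1]`, unrounded.
#' @export
gc_skew <- function(g_pct, c_pct) {
  if (g_pct + c_pct <= 0) stop("undefined skew: G + C = 0", call. = FALSE)
  (g_pct - c_pct) / (g_pct + c_pct)
}

#' Report-ready composition row
#'
#' Rounds half-away-from-zero to the report precisions: percentages to 1
#' decimal, skews to 3 decimals.
#'
#' @param profile a `CompositionProfile`.
#' @param accession,region identifiers carried into the row.
#' @return one-row data.frame with columns `accession`, `region`,
#'   `strand_label`, `A`, `C`, `G`, `T`, `pct_AT`, `at_skew`, `gc_skew`.
#' @export
format_composition <- function(profile, accession = NA, region = "genome") {
  p <- round_half_away(profile$pct, 1)
  data.frame(accession = accession, region = region,
             strand_label = profile$strand_label,
             A = p[["A"]], C = p[["C"]], G = p[["G"]], T = p[["T"]],
             pct_AT = round_half_away(profile$at_content, 1),
             at_skew = round_half_away(profile$at_skew, 3),
             gc_skew = round_half_away(profile$gc_skew, 3),
             stringsAsFactors = FALSE)
}

#' Mixed-convention skew report for a genome
#'
#' Convenience report emitting, per record, the heavy-strand and
#' light-strand composition rows plus a `mixed` row that combines the AT
#' skew of the heavy strand with the GC skew of the light strand. The mixed
#' convention is the only one under which the published skew pairs are
#' reproducible from the published strand compositions; both pure per-strand
#' rows are always emitted alongside.
#'
#' @param genome a `MitoGenome`.
#' @return data.frame with one row per strand plus the `mixed` row.
#' @export
skew_report <- function(genome) {
  heavy_seq <- if (genome$heavy_strand == "plus") genome$sequence
               else revcomp(genome$sequence)
  light_seq <- revcomp(heavy_seq)
  h <- composition(heavy_seq, "heavy")
  l <- composition(light_seq, "light")
  rows <- rbind(format_composition(h, genome$accession),
                format_composition(l, genome$accession))
  mixed <- rows[1, ]
  mixed$strand_label <- "mixed"
  mixed$gc_skew <- round_half_away(l$gc_skew, 3)
  rbind(rows, mixed)
}

## ---- codon usage ----------------------------------------------------------

#' Codon usage and relative synonymous codon usage (RSCU)
#'
#' Counts codons over the concatenation of the supplied in-frame coding
#' sequences; RSCU is computed per synonymous family under the invertebrate
#' mitochondrial code (a codon's count divided by the mean count of its
#' family, so values within a family average to 1).
#'
#' @param cds_list list (or vector) of coding sequences, each with length a
#'   multiple of 3.
#' @return data.frame of class `CodonUsageTable` with columns `codon`, `aa`,
#'   `count`, `per_thousand`, `rscu`.
#' @export
codon_usage <- function(cds_list) {
  cds_list <- unlist(cds_list, use.names = FALSE)
  bad <- nchar(cds_list) %% 3 != 0
  if (any(bad))
    stop("frame error: sequence(s) ", paste(which(bad), collapse = ", "),
         " not a multiple of 3", call. = FALSE)
  cods <- unlist(lapply(toupper(cds_list), codon_split), use.names = FALSE)
  code <- mito_genetic_code()
  counts <- table(factor(cods, levels = names(code)))
  tot <- sum(counts)
  rscu <- rep(NA_real_, length(counts))
  for (aa in unique(code)) {
    fam <- which(code == aa)
    famtot <- sum(counts[fam])
    if (famtot > 0) rscu[fam] <- as.numeric(counts[fam]) / (famtot / length(fam))
  }
  out <- data.frame(codon = names(code), aa = unname(code),
                    count = as.integer(counts),
                    per_thousand = if (tot > 0) 1000 * as.numeric(counts) / tot
                                   else NA_real_,
                    rscu = rscu, stringsAsFactors = FALSE)
  class(out) <- c("CodonUsageTable", "data.frame")
  out
}
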