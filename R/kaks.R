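## selection_kaks: codon-level Ka/Ks estimation (NG86 counting with
## Jukes-Cantor correction) for depth-matched species pairs, per gene and in
## sliding windows, with Fisher exact significance.
##
## Definitions: Ka = dN = S_A / L_A (nonsynonymous substitutions per
## nonsynonymous site), Ks = dS = S_S / L_S, omega = Ka / Ks. Multi-
## nucleotide codon differences are averaged over all minimal substitution
## pathways (equal weights); pathways through stop codons are excluded
## unless every pathway is blocked. All counting uses the invertebrate
## mitochondrial code.

## ---- per-codon site partition and pathway counting ------------------------

.kaks_env <- new.env(parent = emptyenv())

.codon_sites <- function() {
  if (!is.null(.kaks_env$sites)) return(.kaks_env$sites)
  code <- mito_genetic_code()
  bases <- c("A", "C", "G", "T")
  sense <- names(code)[code != "*"]
  syn <- setNames(numeric(length(sense)), sense)
  for (cod in sense) {
    s_tot <- 0
    for (p in 1:3) {
      cs <- strsplit(cod, "")[[1]]
      alts <- setdiff(bases, cs[p])
      n_syn <- 0; n_valid <- 0
      for (b in alts) {
        cs2 <- cs; cs2[p] <- b
        cod2 <- paste(cs2, collapse = "")
        if (code[[cod2]] == "*") next   # stop-producing changes excluded
        n_valid <- n_valid + 1
        if (code[[cod2]] == code[[cod]]) n_syn <- n_syn + 1
      }
      s_tot <- s_tot + if (n_valid > 0) n_syn / n_valid else 0
    }
    syn[[cod]] <- s_tot
  }
  .kaks_env$sites <- syn
  syn
}

## pathway-averaged (syn, nonsyn) substitution counts between two codons
.codon_path_counts <- function(c1, c2) {
  key <- paste0(c1, c2)
  if (is.null(.kaks_env$paths))
    .kaks_env$paths <- new.env(parent = emptyenv())
  if (exists(key, envir = .kaks_env$paths, inherits = FALSE))
    return(get(key, envir = .kaks_env$paths))
  code <- mito_genetic_code()
  d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  res <- c(syn = 0, nonsyn = 0)
  if (length(d) > 0) {
    perms <- .permutations(d)
    step_counts <- function(order_) {
      cur <- strsplit(c1, "")[[1]]
      tgt <- strsplit(c2, "")[[1]]
      s <- 0; ns <- 0
      for (p in order_) {
        aa1 <- code[[paste(cur, collapse = "")]]
        cur[p] <- tgt[p]
        cod2 <- paste(cur, collapse = "")
        aa2 <- code[[cod2]]
        if (aa2 == "*" || aa1 == "*") return(NULL)  # blocked pathway
        if (aa1 == aa2) s <- s + 1 else ns <- ns + 1
      }
      c(s, ns)
    }
    counts <- lapply(perms, step_counts)
    ok <- counts[!vapply(counts, is.null, logical(1))]
    if (length(ok) == 0L) {       # all pathways blocked: fall back to all
      ok <- lapply(perms, function(order_) {
        cur <- strsplit(c1, "")[[1]]; tgt <- strsplit(c2, "")[[1]]
        s <- 0; ns <- 0
        for (p in order_) {
          aa1 <- code[[paste(cur, collapse = "")]]
          cur[p] <- tgt[p]
          aa2 <- code[[paste(cur, collapse = "")]]
          if (!is.na(aa1) && !is.na(aa2) && aa1 == aa2 && aa1 != "*")
            s <- s + 1 else ns <- ns + 1
        }
        c(s, ns)
      })
    }
    m <- do.call(rbind, ok)
    res <- c(syn = mean(m[, 1]), nonsyn = mean(m[, 2]))
  }
  assign(key, res, envir = .kaks_env$paths)
  res
}

.permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in .permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], p)
  out
}

## ---- codon alignment -------------------------------------------------------

#' Codon alignment of two coding sequences
#'
#' Translation-guided alignment: the two sequences are translated with the
#' invertebrate mitochondrial code, globally aligned at the amino-acid level
#' (BLOSUM62, affine gaps), and the alignment is back-threaded onto codons.
#' Columns containing a gap or a stop codon are masked (excluded from
#' counting but reported).
#'
#' @param cds1,cds2 in-frame coding sequences (length a multiple of 3).
#' @param gene optional canonical PCG symbol carried into results.
#' @return list of class `CodonAlignment`: `codons1`, `codons2` (equal-length
#'   codon vectors), `masked` (logical), `gene`, `n_codons` (unmasked count).
#' @export
codon_align <- function(cds1, cds2, gene = NA_character_) {
  cds1 <- toupper(cds1); cds2 <- toupper(cds2)
  if (nchar(cds1) %% 3 != 0 || nchar(cds2) %% 3 != 0)
    stop("coding sequences must be in frame (length multiple of 3)",
         call. = FALSE)
  aa1 <- translate_mito(cds1); aa2 <- translate_mito(cds2)
  if (nchar(aa1) == 0 || nchar(aa2) == 0)
    stop("alignment error: empty translation", call. = FALSE)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(chartr("*", "X", aa1)),
    Biostrings::AAString(chartr("*", "X", aa2)),
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = 10, gapExtension = 0.5, type = "global")
  p1 <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  p2 <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  cods1 <- codon_split(cds1); cods2 <- codon_split(cds2)
  i1 <- 0L; i2 <- 0L
  col1 <- character(length(p1)); col2 <- character(length(p1))
  for (k in seq_along(p1)) {
    if (p1[k] == "-") col1[k] <- "---" else { i1 <- i1 + 1L; col1[k] <- cods1[i1] }
    if (p2[k] == "-") col2[k] <- "---" else { i2 <- i2 + 1L; col2[k] <- cods2[i2] }
  }
  code <- mito_genetic_code()
  is_stop <- function(cod) !is.na(code[cod]) & code[cod] == "*"
  masked <- unname(col1 == "---" | col2 == "---" | is_stop(col1) |
                     is_stop(col2) | grepl("N", col1) | grepl("N", col2))
  idn <- mean(p1[p1 != "-" & p2 != "-"] == p2[p1 != "-" & p2 != "-"])
  if (!is.nan(idn) && idn < 0.30)
    warning("translated identity below 30% - alignment may be unreliable",
            call. = FALSE)
  if (all(masked))
    stop("alignment error: no unmasked codon columns", call. = FALSE)
  structure(list(codons1 = col1, codons2 = col2, masked = masked,
                 gene = gene, n_codons = sum(!masked)),
            class = "CodonAlignment")
}

## internal: alignment object from pre-aligned codon vectors
.codon_alignment <- function(codons1, codons2, gene = NA_character_) {
  code <- mito_genetic_code()
  is_stop <- function(cod) !is.na(code[cod]) & code[cod] == "*"
  masked <- unname(codons1 == "---" | codons2 == "---" |
                     is_stop(codons1) | is_stop(codons2))
  structure(list(codons1 = codons1, codons2 = codons2, masked = masked,
                 gene = gene, n_codons = sum(!masked)),
            class = "CodonAlignment")
}

## ---- NG86 estimation -------------------------------------------------------

#' NG86 Ka/Ks estimate for a codon alignment
#'
#' Site counting partitions each codon position by its mutational fates
#' under the invertebrate mitochondrial code (stop-producing changes
#' excluded; synonymous site fraction averaged over the two sequences).
#' Substitutions between differing codons are averaged over all minimal
#' substitution pathways with equal weights. The Jukes-Cantor correction
#' `d = -3/4 log(1 - 4p/3)` is applied to both proportions.
#'
#' @param aln a `CodonAlignment` with at least 10 unmasked codons (relaxed
#'   via `min_codons` for toy examples).
#' @param min_codons minimum number of unmasked codons (default 10).
#' @return list of class `KaKsEstimate`: `S_A`, `S_S` (pathway-averaged
#'   substitution counts), `L_A`, `L_S` (site counts), `Ka`, `Ks`, `omega`
#'   (0 when Ka = 0 and Ks > 0; `NA` with `omega_undefined = TRUE` when
#'   Ks = 0), `p_fisher`, `gene`, `n_codons`.
#' @export
kaks_ng86 <- function(aln, min_codons = 10L) {
  c1 <- aln$codons1[!aln$masked]
  c2 <- aln$codons2[!aln$masked]
  n <- length(c1)
  if (n < min_codons)
    stop("need >= ", min_codons, " unmasked codons (got ", n, ")",
         call. = FALSE)
  sites <- .codon_sites()
  Ls1 <- sum(sites[c1]); Ls2 <- sum(sites[c2])
  L_S <- (Ls1 + Ls2) / 2
  L_A <- 3 * n - L_S
  S_S <- 0; S_A <- 0
  diff <- which(c1 != c2)
  for (i in diff) {
    cnt <- .codon_path_counts(c1[i], c2[i])
    S_S <- S_S + cnt[["syn"]]
    S_A <- S_A + cnt[["nonsyn"]]
  }
  jc <- function(p) {
    if (p >= 0.75)
      stop("saturation error: proportion ", signif(p, 3),
           " >= 0.75, Jukes-Cantor correction undefined", call. = FALSE)
    if (p == 0) 0 else -0.75 * log(1 - 4 * p / 3)
  }
  Ks <- if (L_S > 0) jc(S_S / L_S) else NA_real_
  Ka <- if (L_A > 0) jc(S_A / L_A) else NA_real_
  omega_undef <- is.na(Ks) || Ks == 0
  omega <- if (omega_undef) NA_real_
           else if (Ka == 0) 0 else Ka / Ks
  est <- structure(list(S_A = S_A, S_S = S_S, L_A = L_A, L_S = L_S,
                        Ka = Ka, Ks = Ks, omega = omega,
                        omega_undefined = omega_undef,
                        p_fisher = NA_real_, gene = aln$gene, n_codons = n),
                   class = "KaKsEstimate")
  est$p_fisher <- fisher_exact(est)
  est
}

#' @export
print.KaKsEstimate <- function(x, ...) {
  cat(sprintf("KaKsEstimate%s: Ka=%.5g Ks=%.5g omega=%s p=%.3g (n=%d codons)\n",
              if (is.na(x$gene)) "" else paste0(" [", x$gene, "]"),
              x$Ka, x$Ks,
              if (x$omega_undefined) "undefined" else sprintf("%.5g", x$omega),
              x$p_fisher, x$n_codons))
  invisible(x)
}

#' Fisher exact test for a Ka/Ks estimate
#'
#' Two-sided exact hypergeometric p-value on the 2x2 table
#' `[[S_A, L_A - S_A], [S_S, L_S - S_S]]` (substituted vs non-substituted
#' sites, rows nonsynonymous/synonymous), with real-valued counts rounded
#' half-away-from-zero to integers. Degenerate tables (a zero margin, e.g.
#' no substitutions at all) give p = 1.
#'
#' @param est a `KaKsEstimate`.
#' @return p-value in `(0, 1]`.
#' @export
fisher_exact <- function(est) {
  sa <- round_half_away(est$S_A); ss <- round_half_away(est$S_S)
  la <- round_half_away(est$L_A); ls <- round_half_away(est$L_S)
  sa <- min(sa, la); ss <- min(ss, ls)
  tab <- matrix(c(sa, la - sa, ss, ls - ss), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  p <- stats::fisher.test(tab)$p.value
  max(min(p, 1), .Machine$double.xmin)
}

## ---- sliding windows --------------------------------------------------------

#' Sliding-window Ka/Ks scan along a codon alignment
#'
#' Windows tile `[0, n_codons - window]` at the given step (codon units,
#' zero-based starts); a trailing partial window is dropped. Windows where
#' Ks = 0 are flagged, not dropped.
#'
#' @param aln a `CodonAlignment` with `n_codons >= window` columns.
#' @param window window length in codons (default 52).
#' @param step step size in codons (default 12).
#' @return data.frame of class `WindowScan` with columns `gene`,
#'   `window_start_codon`, `S_A`, `S_S`, `L_A`, `L_S`, `Ka`, `Ks`, `omega`,
#'   `omega_undefined`, `p_fisher`.
#' @export
sliding_window <- function(aln, window = 52L, step = 12L) {
  ncol_ <- length(aln$codons1)
  if (ncol_ < window)
    stop("alignment shorter than one window", call. = FALSE)
  starts <- seq(0L, ncol_ - window, by = step)
  rows <- lapply(starts, function(s) {
    idx <- (s + 1L):(s + window)
    sub <- .codon_alignment(aln$codons1[idx], aln$codons2[idx], aln$gene)
    est <- kaks_ng86(sub, min_codons = 1L)
    data.frame(gene = aln$gene, window_start_codon = s,
               S_A = est$S_A, S_S = est$S_S, L_A = est$L_A, L_S = est$L_S,
               Ka = est$Ka, Ks = est$Ks,
               omega = ifelse(est$omega_undefined, NA_real_, est$omega),
               omega_undefined = est$omega_undefined,
               p_fisher = est$p_fisher, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("WindowScan", "data.frame")
  attr(out, "window") <- window
  attr(out, "step") <- step
  out
}

#' Classify the selection regime from an omega value
#'
#' `omega < 1` purifying, `> 1` positive (diversifying), with a neutrality
#' tolerance band `|omega - 1| <= band` classified as neutral.
#'
#' @param omega Ka/Ks ratio (must be defined).
#' @param band half-width of the neutral band (default 0.05).
#' @return one of `"purifying"`, `"neutral"`, `"positive"`.
#' @export
classify_selection <- function(omega, band = 0.05) {
  if (is.na(omega)) stop("omega undefined", call. = FALSE)
  if (abs(omega - 1) <= band) "neutral"
  else if (omega > 1) "positive" else "purifying"
}

## ---- depth-matched pair report ----------------------------------------------

## report order of the 13 PCGs (as printed in pairwise selection tables)
.PCG_REPORT_ORDER <- c("cox1", "cox2", "nad3", "nad2", "atp8", "atp6", "cox3",
                       "nad5", "nad4", "nad4L", "nad6", "cob", "nad1")

#' Per-gene Ka/Ks report for depth-matched genome pairs
#'
#' For each pair of annotated genomes, aligns and estimates every one of
#' the 13 protein-coding genes (missing genes are reported and skipped) and
#' returns a long table of 13 rows per pair in the conventional order.
#'
#' @param pairs list of pairs; each element a list with `g1`, `g2`
#'   (`MitoGenome`s) and optional `label`, `depth1`, `depth2`.
#' @return data.frame with columns `pair`, `depth1`, `depth2`, `pcg_no`,
#'   `gene`, `Ka`, `Ks`, `omega`, `p_fisher`, `regime`.
#' @export
depth_pair_report <- function(pairs) {
  rows <- list()
  for (pr in pairs) {
    lab <- if (!is.null(pr$label)) pr$label
           else paste(pr$g1$accession, pr$g2$accession, sep = " vs ")
    for (k in seq_along(.PCG_REPORT_ORDER)) {
      gene <- .PCG_REPORT_ORDER[k]
      have1 <- gene %in% pr$g1$features$name
      have2 <- gene %in% pr$g2$features$name
      if (!have1 || !have2) {
        warning("gene ", gene, " missing in pair ", lab, "; skipped",
                call. = FALSE)
        next
      }
      est <- kaks_ng86(codon_align(extract_cds(pr$g1, gene),
                                   extract_cds(pr$g2, gene), gene = gene))
      rows[[length(rows) + 1L]] <- data.frame(
        pair = lab,
        depth1 = if (is.null(pr$depth1)) NA_character_ else pr$depth1,
        depth2 = if (is.null(pr$depth2)) NA_character_ else pr$depth2,
        pcg_no = k, gene = gene, Ka = est$Ka, Ks = est$Ks,
        omega = ifelse(est$omega_undefined, NA_real_, est$omega),
        p_fisher = est$p_fisher,
        regime = if (est$omega_undefined) NA_character_
                 else classify_selection(est$omega),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
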