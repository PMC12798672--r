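## Canonical 37-gene mitochondrial vocabulary (+ CR) and synonym mapping.
## Metazoan mitogenomes carry 13 protein-coding genes, 22 tRNAs and 2 rRNAs;
## the control region (CR) is the major non-coding segment.

.PCGS <- c("cox1", "cox2", "cox3", "cob", "nad1", "nad2", "nad3", "nad4",
           "nad4L", "nad5", "nad6", "atp6", "atp8")

.TRNAS <- c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH", "trnI",
            "trnK", "trnL1", "trnL2", "trnM", "trnN", "trnP", "trnQ", "trnR",
            "trnS1", "trnS2", "trnT", "trnV", "trnW", "trnY")

.RRNAS <- c("rrnL", "rrnS")

#' Canonical mitochondrial gene vocabulary
#'
#' Returns the closed 38-symbol vocabulary used throughout the package:
#' 13 protein-coding genes, 22 tRNAs (with `trnL1`/`trnL2` and
#' `trnS1`/`trnS2` disambiguated by anticodon), two rRNAs, and `CR` for the
#' control region.
#'
#' @param include_cr include the `CR` symbol (default `TRUE`).
#' @return character vector of canonical symbols.
#' @export
gene_vocabulary <- function(include_cr = TRUE) {
  v <- c(.PCGS, .TRNAS, .RRNAS)
  if (include_cr) v <- c(v, "CR")
  v
}

#' Kind of a canonical gene symbol
#'
#' @param name canonical symbol(s).
#' @return character vector over `{PCG, tRNA, rRNA, CR}` (`NA` if unknown).
#' @export
gene_kind <- function(name) {
  base <- sub("_copy[0-9]+$", "", name)
  out <- rep(NA_character_, length(base))
  out[base %in% .PCGS] <- "PCG"
  out[base %in% .TRNAS] <- "tRNA"
  out[base %in% .RRNAS] <- "rRNA"
  out[base == "CR"] <- "CR"
  out
}

## Anticodon -> canonical symbol for the duplicated leucine/serine tRNAs
## (Fig.-style convention: L1 = tag, L2 = taa, S1 = tct, S2 = tga).
.ANTICODON_MAP <- c(tag = "trnL1", taa = "trnL2", tct = "trnS1", tga = "trnS2",
                    uag = "trnL1", uaa = "trnL2", ucu = "trnS1", uga = "trnS2")

## One-letter amino acid -> tRNA symbol (unambiguous tRNAs only)
.AA1_TRNA <- c(A = "trnA", C = "trnC", D = "trnD", E = "trnE", F = "trnF",
               G = "trnG", H = "trnH", I = "trnI", K = "trnK", M = "trnM",
               N = "trnN", P = "trnP", Q = "trnQ", R = "trnR", T = "trnT",
               V = "trnV", W = "trnW", Y = "trnY")

.AA3_AA1 <- c(ala = "A", arg = "R", asn = "N", asp = "D", cys = "C",
              gln = "Q", glu = "E", gly = "G", his = "H", ile = "I",
              leu = "L", lys = "K", met = "M", phe = "F", pro = "P",
              ser = "S", thr = "T", trp = "W", tyr = "Y", val = "V")

#' Load the gene-name synonym table
#'
#' The table shipped under `inst/extdata/gene_synonyms.csv` maps the
#' heterogeneous gene labels found in GenBank annotations (e.g. `"COI"`,
#' `"ND4L"`, `"D-loop"`, `"l-rRNA"`) onto the canonical vocabulary. Users may
#' supply their own table with the same two columns (`synonym`, `canonical`).
#'
#' @param path optional path to an alternative CSV.
#' @return data.frame with columns `synonym`, `canonical`.
#' @export
gene_synonyms <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "gene_synonyms.csv", package = "anomito")
  read.csv(path, stringsAsFactors = FALSE)
}

.norm_label <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Map a raw gene label to its canonical symbol
#'
#' Matching is case- and punctuation-insensitive and consults, in order: the
#' synonym table, an embedded anticodon (e.g. `"trnL(taa)"` maps to `trnL2`),
#' and three-letter / one-letter tRNA product names (`"tRNA-Leu"` alone is
#' ambiguous and returns `NA` unless an anticodon or L1/L2 tag resolves it).
#' The mapping is idempotent: canonical symbols map to themselves.
#'
#' @param label character vector of raw labels.
#' @param synonyms synonym table as from [gene_synonyms()].
#' @return character vector of canonical symbols (`NA` where unmappable).
#' @export
canonical_gene_name <- function(label, synonyms = gene_synonyms()) {
  vapply(label, function(lab) {
    if (is.na(lab) || !nzchar(lab)) return(NA_character_)
    if (lab %in% gene_vocabulary()) return(lab)  # idempotence
    key <- .norm_label(lab)
    vkey <- .norm_label(gene_vocabulary())
    hit <- match(key, vkey)
    if (!is.na(hit)) return(gene_vocabulary()[hit])
    skey <- .norm_label(synonyms$synonym)
    hit <- match(key, skey)
    if (!is.na(hit)) return(synonyms$canonical[hit])
    ## anticodon in parentheses or trailing, e.g. trnL(taa), tRNA-Leu-UAA
    ac <- regmatches(lab, regexpr("(?i)(?<=[-(])[acgtu]{3}(?=\\)?$)", lab,
                                  perl = TRUE))
    if (length(ac) == 1L) {
      acm <- .ANTICODON_MAP[tolower(ac)]
      if (!is.na(acm)) return(unname(acm))
    }
    ## explicit L1/L2/S1/S2 tags
    tag <- regmatches(key, regexpr("(trn|trna)?(l1|l2|s1|s2)$", key))
    if (length(tag) == 1L) {
      t2 <- sub("^(trn|trna)", "", tag)
      return(paste0("trn", toupper(substr(t2, 1, 1)), substr(t2, 2, 2)))
    }
    ## tRNA by amino-acid name: trna-ala, trnA, tRNA-Trp ...
    m <- regmatches(key, regexpr("^trna?([a-z]+)$", key))
    if (length(m) == 1L) {
      aa <- sub("^trna?", "", key)
      if (aa %in% names(.AA3_AA1)) aa <- unname(.AA3_AA1[aa])
      aa <- toupper(aa)
      if (aa %in% names(.AA1_TRNA)) return(unname(.AA1_TRNA[aa]))
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
}
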