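## mito_io: annotated-mitogenome input/output, canonical naming, control-
## region location, CDS extraction.
##
## Coordinates are 1-based inclusive on the deposited plus strand (GenBank
## convention). A feature that spans the circular origin is stored with
## start > end and `wraps = TRUE`. The deposited plus strand is treated as
## the heavy strand for skew bookkeeping (override per record via
## `heavy_strand`).

#' Construct a MitoGenome object
#'
#' @param accession text identifier.
#' @param sequence DNA string over `{A,C,G,T,N}` (uppercased on input),
#'   representing the deposited plus strand.
#' @param features data.frame with columns `name` (canonical symbol),
#'   `start`, `end` (1-based inclusive), `strand` (`"+"`/`"-"`), `kind`
#'   (`PCG`/`tRNA`/`rRNA`/`CR`), and optionally `wraps` (logical).
#' @param taxon organism name.
#' @param circular logical; mitogenomes are circular.
#' @param heavy_strand which deposited strand is labelled "heavy" for skew
#'   bookkeeping: `"plus"` (default) or `"minus"`.
#' @return object of class `MitoGenome`.
#' @export
mito_genome <- function(accession, sequence, features, taxon = accession,
                        circular = TRUE, heavy_strand = c("plus", "minus")) {
  heavy_strand <- match.arg(heavy_strand)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("empty sequence", call. = FALSE)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  if (is.null(features$wraps)) features$wraps <- features$start > features$end
  features <- features[, c("name", "start", "end", "strand", "kind", "wraps")]
  L <- nchar(sequence)
  bad <- features$start < 1 | features$start > L | features$end < 1 |
    features$end > L
  if (any(bad))
    stop("feature coordinates outside [1, ", L, "]: ",
         paste(features$name[bad], collapse = ", "), call. = FALSE)
  g <- structure(list(accession = accession, taxon = taxon,
                      sequence = sequence, circular = circular,
                      heavy_strand = heavy_strand,
                      features = features),
                 class = "MitoGenome")
  .check_pcg_overlap(g)
  g
}

.check_pcg_overlap <- function(g, max_overlap = 10L) {
  f <- g$features[g$features$kind == "PCG" & !g$features$wraps, , drop = FALSE]
  if (nrow(f) < 2) return(invisible(TRUE))
  for (s in c("+", "-")) {
    fs <- f[f$strand == s, , drop = FALSE]
    if (nrow(fs) < 2) next
    fs <- fs[order(fs$start), ]
    ov <- fs$end[-nrow(fs)] - fs$start[-1] + 1L
    if (any(ov > max_overlap))
      warning("PCG features overlap by more than ", max_overlap,
              " bp on strand ", s, " in ", g$accession, call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.MitoGenome <- function(x, ...) {
  cat("MitoGenome", x$accession, paste0("(", x$taxon, ")"), "\n")
  cat("  length:", nchar(x$sequence), "bp,",
      if (x$circular) "circular" else "linear", "\n")
  k <- table(x$features$kind)
  cat("  features:", nrow(x$features),
      paste0("(", paste(names(k), k, sep = ":", collapse = ", "), ")"), "\n")
  invisible(x)
}

#' Length of a MitoGenome sequence
#' @param genome a `MitoGenome`.
#' @return integer length in bp.
#' @export
genome_length <- function(genome) nchar(genome$sequence)

## ---- GenBank flat-file I/O ------------------------------------------------

.parse_location <- function(loc) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  wraps <- FALSE
  if (grepl("^(join|order)\\(", loc)) {
    inner <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
    parts <- strsplit(inner, ",")[[1]]
    first <- parts[1]; last <- parts[length(parts)]
    start <- as.integer(sub("\\.\\..*$", "", first))
    end <- as.integer(sub("^.*\\.\\.", "", last))
    wraps <- TRUE
  } else if (grepl("\\.\\.", loc)) {
    start <- as.integer(sub("\\.\\..*$", "", loc))
    end <- as.integer(sub("^.*\\.\\.", "", loc))
  } else {
    start <- end <- as.integer(loc)
  }
  if (is.na(start) || is.na(end)) return(NULL)
  list(start = start, end = end, strand = strand,
       wraps = wraps && start > end)
}

#' Read a GenBank flat file into a MitoGenome
#'
#' Parses a single-record GenBank flat file (LOCUS/FEATURES/ORIGIN), maps
#' every gene, CDS, tRNA, rRNA and D-loop feature onto the canonical
#' 37-gene + CR vocabulary via [canonical_gene_name()], and returns the
#' uppercase plus-strand sequence. Features whose labels cannot be mapped
#' are reported in `attr(x, "unmapped")`.
#'
#' @param path path to a `.gb` flat file.
#' @param synonyms synonym table, see [gene_synonyms()].
#' @return a [mito_genome()] object.
#' @export
read_genbank <- function(path, synonyms = gene_synonyms()) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^LOCUS", lines[1]))
    stop("not a GenBank flat file: ", path, call. = FALSE)
  locus <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  accession <- locus[2]
  circular <- any(grepl("circular", lines[1], ignore.case = TRUE))
  org <- grep("^  ORGANISM", lines, value = TRUE)
  taxon <- if (length(org)) trimws(sub("^  ORGANISM", "", org[1])) else accession

  feat_start <- grep("^FEATURES", lines)
  orig_start <- grep("^ORIGIN", lines)
  if (length(feat_start) == 0L || length(orig_start) == 0L)
    stop("malformed GenBank record (missing FEATURES or ORIGIN): ", path,
         call. = FALSE)

  ## sequence
  seq_lines <- lines[(orig_start[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (grepl("[^ACGTN]", sequence))
    sequence <- gsub("[^ACGTN]", "N", sequence)

  ## feature table
  flines <- lines[(feat_start[1] + 1L):(orig_start[1] - 1L)]
  feats <- list(); cur <- NULL
  for (ln in flines) {
    if (grepl("^ {5}\\S", ln)) {
      if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
      key <- sub("^ {5}(\\S+).*$", "\\1", ln)
      loc <- trimws(sub("^ {5}\\S+", "", ln))
      cur <- list(key = key, loc = loc, quals = character(0))
    } else if (!is.null(cur)) {
      txt <- trimws(ln)
      if (startsWith(txt, "/")) {
        cur$quals <- c(cur$quals, txt)
      } else if (length(cur$quals) == 0L) {
        cur$loc <- paste0(cur$loc, txt)  # continued location
      } else {
        n <- length(cur$quals)
        cur$quals[n] <- paste(cur$quals[n], txt)
      }
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur

  qual_value <- function(quals, name) {
    hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    gsub("\"", "", sub(paste0("^/", name, "="), "", hit[1]))
  }

  rows <- list(); unmapped <- character(0)
  for (f in feats) {
    if (!f$key %in% c("gene", "CDS", "tRNA", "rRNA", "D-loop", "misc_feature"))
      next
    loc <- .parse_location(f$loc)
    if (is.null(loc)) next
    labels <- c(qual_value(f$quals, "gene"), qual_value(f$quals, "product"),
                qual_value(f$quals, "note"))
    labels <- labels[!is.na(labels)]
    if (f$key == "D-loop") labels <- c(labels, "D-loop")
    if (f$key == "misc_feature" &&
        !any(grepl("control region|D-loop|A\\+T", labels, ignore.case = TRUE)))
      next
    name <- NA_character_
    for (lab in labels) {
      name <- canonical_gene_name(lab, synonyms)
      if (!is.na(name)) break
    }
    ## disambiguate Leu/Ser tRNAs via anticodon in any qualifier text
    if (is.na(name) && f$key == "tRNA") {
      all_txt <- paste(labels, collapse = " ")
      ac <- regmatches(all_txt,
                       regexpr("(?i)\\(([acgtu]{3})\\)", all_txt, perl = TRUE))
      if (length(ac) == 1L) {
        acm <- .ANTICODON_MAP[tolower(gsub("[()]", "", ac))]
        if (!is.na(acm)) name <- unname(acm)
      }
    }
    if (is.na(name)) {
      if (length(labels)) unmapped <- c(unmapped, labels[1])
      next
    }
    kind <- switch(f$key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                   "D-loop" = "CR", misc_feature = "CR",
                   gene = gene_kind(name))
    rows[[length(rows) + 1L]] <-
      data.frame(name = name, start = loc$start, end = loc$end,
                 strand = loc$strand, kind = kind, wraps = loc$wraps,
                 typed = f$key != "gene", stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop("annotation error: no mappable features in record ", accession,
         call. = FALSE)
  tab <- do.call(rbind, rows)
  ## prefer typed features over bare 'gene' duplicates of the same symbol
  tab <- tab[order(tab$name, -as.integer(tab$typed)), ]
  tab <- tab[!duplicated(tab[, c("name", "start", "strand")]), ]
  ## a 'gene' twin may differ by a stop codon from its CDS: drop by name+overlap
  keep <- rep(TRUE, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (tab$typed[i]) next
    same <- which(tab$typed & tab$name == tab$name[i] &
                    tab$strand == tab$strand[i] &
                    abs(tab$start - tab$start[i]) <= 5)
    if (length(same)) keep[i] <- FALSE
  }
  tab <- tab[keep, ]
  ## duplicated genes (e.g. lithodid tRNA duplications) -> gene_copy2, ...
  dup <- duplicated(tab$name)
  if (any(dup)) {
    for (nm in unique(tab$name[dup])) {
      idx <- which(tab$name == nm)
      idx <- idx[order(tab$start[idx])]
      if (length(idx) > 1)
        tab$name[idx[-1]] <- paste0(nm, "_copy", seq_along(idx[-1]) + 1L)
    }
  }
  tab <- tab[order(tab$start), ]
  g <- mito_genome(accession, sequence, tab[, 1:6], taxon = taxon,
                   circular = circular)
  attr(g, "unmapped") <- unique(unmapped)
  g
}

#' Write a MitoGenome as a GenBank flat file
#'
#' Minimal writer used by the synthetic-genome generator; emits LOCUS,
#' ORGANISM, FEATURES (CDS/tRNA/rRNA/D-loop with `/gene` qualifiers) and
#' ORIGIN blocks that [read_genbank()] round-trips.
#'
#' @param genome a `MitoGenome`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  L <- genome_length(genome)
  con <- file(path, "w"); on.exit(close(con))
  top <- if (genome$circular) "circular" else "linear"
  writeLines(sprintf("LOCUS       %s%17d bp    DNA     %s INV 01-JAN-2026",
                     genome$accession, L, top), con)
  writeLines(sprintf("DEFINITION  %s mitochondrion, complete genome.",
                     genome$taxon), con)
  writeLines(sprintf("  ORGANISM  %s", genome$taxon), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  writeLines(sprintf('                     /organism="%s"', genome$taxon), con)
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    key <- switch(f$kind[i], PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  CR = "D-loop")
    loc <- if (isTRUE(f$wraps[i]))
      sprintf("join(%d..%d,1..%d)", f$start[i], L, f$end[i])
    else sprintf("%d..%d", f$start[i], f$end[i])
    if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-16s%s", key, loc), con)
    writeLines(sprintf('                     /gene="%s"', f$name[i]), con)
  }
  writeLines("ORIGIN", con)
  s <- genome$sequence
  for (off in seq(1L, nchar(s), 60L)) {
    chunk <- substr(s, off, min(off + 59L, nchar(s)))
    grp <- paste(substring(chunk, seq(1, nchar(chunk), 10),
                           pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk))),
                 collapse = " ")
    writeLines(sprintf("%9d %s", off, tolower(grp)), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read FASTA records
#'
#' Sequences are uppercased and U converted to T; headers are retained as
#' identifiers.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("format error reading FASTA: ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- chartr("U", "T", toupper(as.character(set)))
  setNames(seqs, names(set))
}

## ---- control region -------------------------------------------------------

#' Locate the control region of an annotated mitogenome
#'
#' If the annotation carries an explicit CR/D-loop feature it takes
#' precedence; otherwise the single longest unannotated circular gap is
#' returned. In both cases flanking gene symbols are reported. When every
#' gap is shorter than `min_length` the region is flagged `"too compact"`,
#' matching records whose control region could not be delimited.
#'
#' @param genome a `MitoGenome` with at least two features.
#' @param min_length minimum gap length in bp (default 50).
#' @return list of class `IntergenicRegion` with `start`, `end`, `length`,
#'   `flank5`, `flank3`, `wraps`, `status` (`"ok"` or `"too compact"`) and
#'   `sequence`.
#' @export
locate_control_region <- function(genome, min_length = 50L) {
  f <- genome$features
  if (nrow(f) < 2) stop("need >= 2 features", call. = FALSE)
  L <- genome_length(genome)

  cr <- which(f$kind == "CR")
  if (length(cr)) {
    i <- cr[1]
    return(.region_at(genome, f$start[i], f$end[i], isTRUE(f$wraps[i]),
                      status = "ok"))
  }

  covered <- logical(L)
  for (i in seq_len(nrow(f))) {
    if (isTRUE(f$wraps[i])) {
      covered[f$start[i]:L] <- TRUE
      covered[1:f$end[i]] <- TRUE
    } else covered[f$start[i]:f$end[i]] <- TRUE
  }
  if (all(covered))
    return(.too_compact(genome))
  ## runs of uncovered positions on the circle
  idx <- which(!covered)
  brk <- c(0L, which(diff(idx) > 1L), length(idx))
  runs <- data.frame(start = idx[brk[-length(brk)] + 1L], end = idx[brk[-1]])
  ## merge first and last run across the origin
  wraps <- FALSE
  if (nrow(runs) > 1 && runs$start[1] == 1L && runs$end[nrow(runs)] == L) {
    runs$start[1] <- runs$start[nrow(runs)]
    runs <- runs[-nrow(runs), , drop = FALSE]
    if (runs$start[1] > runs$end[1]) runs$wraps0 <- c(TRUE, rep(FALSE, nrow(runs) - 1L))
  }
  len <- ifelse(runs$start <= runs$end, runs$end - runs$start + 1L,
                L - runs$start + 1L + runs$end)
  best <- which.max(len)
  if (len[best] < min_length) return(.too_compact(genome))
  .region_at(genome, runs$start[best], runs$end[best],
             runs$start[best] > runs$end[best], status = "ok")
}

.too_compact <- function(genome) {
  structure(list(start = NA_integer_, end = NA_integer_, length = 0L,
                 flank5 = NA_character_, flank3 = NA_character_,
                 wraps = FALSE, status = "too compact", sequence = ""),
            class = "IntergenicRegion")
}

.region_at <- function(genome, start, end, wraps, status) {
  L <- genome_length(genome)
  f <- genome$features
  len <- if (wraps) L - start + 1L + end else end - start + 1L
  prev_pos <- if (start == 1L) L else start - 1L
  next_pos <- if (end == L) 1L else end + 1L
  covers <- function(pos) {
    which((f$wraps & (f$start <= pos | f$end >= pos)) |
            (!f$wraps & f$start <= pos & f$end >= pos))
  }
  f5 <- covers(prev_pos); f3 <- covers(next_pos)
  flank5 <- if (length(f5)) f$name[f5[which.max(f$end[f5])]] else NA_character_
  flank3 <- if (length(f3)) f$name[f3[which.min(f$start[f3])]] else NA_character_
  seq <- if (wraps)
    paste0(substr(genome$sequence, start, L), substr(genome$sequence, 1, end))
  else substr(genome$sequence, start, end)
  structure(list(start = start, end = end, length = len,
                 flank5 = flank5, flank3 = flank3, wraps = wraps,
                 status = status, sequence = seq),
            class = "IntergenicRegion")
}

#' @export
print.IntergenicRegion <- function(x, ...) {
  if (x$status == "too compact") {
    cat("IntergenicRegion: too compact (no gap >= threshold)\n")
  } else {
    cat(sprintf("IntergenicRegion %d..%d (%d bp) between %s and %s%s\n",
                x$start, x$end, x$length, x$flank5, x$flank3,
                if (x$wraps) " [wraps origin]" else ""))
  }
  invisible(x)
}

## ---- CDS extraction -------------------------------------------------------

#' Extract a protein-coding sequence in coding orientation
#'
#' Minus-strand genes are reverse-complemented; the length is trimmed to a
#' multiple of 3 from the 3' end (incomplete T/TA stops are thereby trimmed,
#' not padded), and a terminal complete stop codon (TAA/TAG under the
#' invertebrate mitochondrial code) is removed. Internal stop codons trigger
#' a warning but the sequence is still returned.
#'
#' @param genome a `MitoGenome`.
#' @param gene canonical PCG symbol.
#' @return DNA string in coding orientation.
#' @export
extract_cds <- function(genome, gene) {
  f <- genome$features
  i <- which(f$name == gene)
  if (length(i) == 0L)
    stop("gene ", gene, " not annotated in ", genome$accession, call. = FALSE)
  i <- i[1]
  L <- genome_length(genome)
  s <- if (isTRUE(f$wraps[i]))
    paste0(substr(genome$sequence, f$start[i], L),
           substr(genome$sequence, 1, f$end[i]))
  else substr(genome$sequence, f$start[i], f$end[i])
  if (f$strand[i] == "-") s <- revcomp(s)
  n <- nchar(s)
  s <- substr(s, 1L, n - n %% 3L)
  cods <- codon_split(s)
  if (length(cods) && cods[length(cods)] %in% c("TAA", "TAG"))
    s <- substr(s, 1L, nchar(s) - 3L)
  aa <- strsplit(translate_mito(s), "")[[1]]
  if (any(aa == "*"))
    warning("internal stop codon(s) in ", gene, " of ", genome$accession,
            call. = FALSE)
  s
}

## ---- tabular gene-feature output ------------------------------------------

#' Write the gene-feature table of one or more genomes as TSV
#'
#' Columns, in fixed order: `accession`, `gene`, `start`, `end`, `strand`,
#' `kind`.
#'
#' @param genomes a `MitoGenome` or list of them.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(genomes, path) {
  if (inherits(genomes, "MitoGenome")) genomes <- list(genomes)
  tabs <- lapply(genomes, function(g) {
    data.frame(accession = g$accession, gene = g$features$name,
               start = g$features$start, end = g$features$end,
               strand = g$features$strand, kind = g$features$kind,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
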