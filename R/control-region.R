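## control_region: tandem repeats (TRF-style k-mer seeding + consensus
## refinement), microsatellites, inverted repeats, and motif-block
## annotation for mitochondrial control regions.

#' Find tandem repeats
#'
#' TRF-style detector: candidate periods are seeded from recurring k-mers
#' at constant spacing, refined by voting a rolling consensus over the
#' candidate array, and scored with the TRF match/mismatch weights
#' (+2 / -7); the reported span is the maximal-scoring contiguous segment.
#' Overlapping reports are merged keeping the highest score (ties to the
#' smaller period). Indels within repeat arrays are not modelled.
#'
#' @param seq DNA string, length >= 2 * `min_period`.
#' @param min_period,max_period period search range in bp.
#' @param min_score minimum alignment score (match +2, mismatch -7) for a
#'   repeat to be reported (default 20).
#' @param min_copies minimum copy number (default 1.9).
#' @param k seed k-mer length (default 5).
#' @return data.frame with columns `period`, `copy_number` (1 decimal),
#'   `start`, `end`, `consensus`, `score`, `percent_matches`; zero rows
#'   when nothing passes the thresholds.
#' @export
find_tandem_repeats <- function(seq, min_period = 1L, max_period = 500L,
                                min_score = 20, min_copies = 1.9, k = 5L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 2 * min_period) stop("sequence shorter than two periods",
                               call. = FALSE)
  ch <- strsplit(seq, "")[[1]]
  max_period <- min(max_period, floor(n / 2))

  ## seed: positions of identical k-mers at spacing d
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  occ <- split(seq_along(kmers), kmers)
  hits <- list()
  for (pos in occ) {
    if (length(pos) < 2) next
    d <- diff(pos)
    keep <- d >= max(min_period, 1) & d <= max_period
    if (any(keep))
      hits[[length(hits) + 1L]] <- cbind(pos = pos[-length(pos)][keep],
                                         d = d[keep])
  }
  ## short periods (< k) seed differently: s[i] == s[i+d] runs
  short <- list()
  for (d in seq(max(1, min_period), min(k - 1, max_period))) {
    eq <- ch[seq_len(n - d)] == ch[(d + 1):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    good <- which(r$values & r$lengths >= d)  # >= 2 copies
    for (g in good)
      short[[length(short) + 1L]] <- c(pos = starts[g], d = d,
                                       len = r$lengths[g])
  }

  cands <- list()
  if (length(hits)) {
    H <- do.call(rbind, hits)
    for (d in sort(unique(H[, "d"]))) {
      pos <- sort(H[H[, "d"] == d, "pos"])
      need <- max(4, round(0.25 * d))
      if (length(pos) < need) next
      ## cluster hit positions closer than d apart
      grp <- cumsum(c(1, diff(pos) > d))
      for (g in unique(grp)) {
        p <- pos[grp == g]
        if (length(p) < need) next
        cands[[length(cands) + 1L]] <- c(start = min(p),
                                         end = min(n, max(p) + d + k - 1L),
                                         d = d)
      }
    }
  }
  for (s in short)
    cands[[length(cands) + 1L]] <- c(start = s[["pos"]],
                                     end = min(n, s[["pos"]] + s[["d"]] +
                                                 s[["len"]] - 1L),
                                     d = s[["d"]])
  if (length(cands) == 0L) return(.empty_tr())

  reports <- list()
  for (cd in cands) {
    rep_ <- .refine_repeat(ch, cd[["start"]], cd[["end"]], cd[["d"]],
                           min_score, min_copies)
    if (!is.null(rep_)) reports[[length(reports) + 1L]] <- rep_
  }
  if (length(reports) == 0L) return(.empty_tr())
  tab <- do.call(rbind, reports)
  tab <- tab[order(-tab$score, tab$period), , drop = FALSE]
  ## merge overlaps: keep highest score
  keep <- rep(TRUE, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(tab))) {
      if (j == i || !keep[j]) next
      ov <- min(tab$end[i], tab$end[j]) - max(tab$start[i], tab$start[j]) + 1
      if (ov > 0.5 * (tab$end[j] - tab$start[j] + 1)) keep[j] <- FALSE
    }
  }
  tab <- tab[keep, , drop = FALSE]
  tab <- tab[order(tab$start), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

.empty_tr <- function() {
  data.frame(period = integer(0), copy_number = numeric(0),
             start = integer(0), end = integer(0),
             consensus = character(0), score = numeric(0),
             percent_matches = numeric(0), stringsAsFactors = FALSE)
}

.refine_repeat <- function(ch, start, end, d, min_score, min_copies) {
  n <- length(ch)
  ## widen by one period each side, then find best segment
  lo <- max(1L, start - d); hi <- min(n, end + d)
  anchor <- start
  idx <- lo:hi
  phase <- (idx - anchor) %% d
  ## consensus by voting
  cons <- character(d)
  for (p in 0:(d - 1)) {
    col <- ch[idx[phase == p]]
    tb <- table(col)
    cons[p + 1] <- names(tb)[which.max(tb)]
  }
  m <- ch[idx] == cons[phase + 1]
  sc <- ifelse(m, 2, -7)
  ## maximal-scoring contiguous segment (Kadane with position recovery)
  best <- 0; cur <- 0; bs <- 0L; be <- -1L; cs <- 1L
  for (t in seq_along(sc)) {
    if (cur <= 0) { cur <- sc[t]; cs <- t } else cur <- cur + sc[t]
    if (cur > best) { best <- cur; bs <- cs; be <- t }
  }
  if (be < bs) return(NULL)
  span <- be - bs + 1L
  copies <- span / d
  if (best < min_score || copies < min_copies) return(NULL)
  seg_idx <- idx[bs:be]
  matches <- sum(m[bs:be])
  ## consensus re-read from the final segment phase-0 anchor
  data.frame(period = as.integer(d),
             copy_number = round(span / d, 1),
             start = seg_idx[1], end = seg_idx[span],
             consensus = paste(cons, collapse = ""),
             score = best,
             percent_matches = round(100 * matches / span, 1),
             stringsAsFactors = FALSE)
}

#' Find simple sequence repeats (microsatellites)
#'
#' Maximal perfect runs of a 1-6 bp unit, scanned left-greedily; a run is
#' reported when its copy number reaches the per-unit-length threshold.
#' Runs whose unit is itself periodic (e.g. `ATAT` for an `AT` run) are
#' suppressed in favour of the primitive unit.
#'
#' @param seq DNA string.
#' @param min_copies named thresholds by unit length (defaults
#'   `1:12, 2:6, 3:4, 4:3, 5:3, 6:3`).
#' @return data.frame with columns `unit`, `copies`, `start`, `end`.
#' @export
find_ssrs <- function(seq,
                      min_copies = c(`1` = 12, `2` = 6, `3` = 4, `4` = 3,
                                     `5` = 3, `6` = 3)) {
  seq <- toupper(seq)
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  out <- list()
  claimed <- logical(n)  # positions already part of a shorter-unit SSR
  for (u in 1:6) {
    thr <- min_copies[[as.character(u)]]
    i <- 1L
    while (i + u * 2L - 1L <= n) {
      unit <- ch[i:(i + u - 1L)]
      ## primitive unit only
      if (u > 1 && any(vapply(1:(u - 1), function(p)
        u %% p == 0 && all(unit == unit[((seq_len(u) - 1) %% p) + 1]),
        logical(1)))) { i <- i + 1L; next }
      j <- i + u
      while (j + u - 1L <= n && all(ch[j:(j + u - 1L)] == unit)) j <- j + u
      copies <- (j - i) %/% u
      if (copies >= thr && !any(claimed[i:(j - 1L)])) {
        out[[length(out) + 1L]] <- data.frame(
          unit = paste(unit, collapse = ""), copies = copies,
          start = i, end = i + copies * u - 1L, stringsAsFactors = FALSE)
        claimed[i:(i + copies * u - 1L)] <- TRUE
        i <- i + copies * u
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(unit = character(0), copies = integer(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  tab <- do.call(rbind, out)
  tab[order(tab$start), , drop = FALSE]
}

#' Find inverted repeats (hairpin arms)
#'
#' Seed-and-extend comparison of the sequence against its reverse
#' complement: exact k-mer seeds are extended greedily in both directions
#' under einverted-style scoring (match +3, mismatch -4; gaps not
#' modelled), and non-overlapping hits are reported by score.
#'
#' @param seq DNA string, length >= 2 * `min_arm`.
#' @param min_arm minimum arm length in bp (default 10).
#' @param max_mismatch_pct maximum percent mismatching positions within an
#'   arm (default 25).
#' @param min_score minimum arm alignment score (default 30 = a perfect
#'   10 bp arm).
#' @param min_loop minimum loop length in nt (default 3).
#' @param k seed length (default 6).
#' @return data.frame with columns `arm_length`, `loop_length`,
#'   `start1`, `end1`, `start2`, `end2`, `matches` (percent), `score`.
#' @export
find_inverted_repeats <- function(seq, min_arm = 10L, max_mismatch_pct = 25,
                                  min_score = 30, min_loop = 3L, k = 6L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 2 * min_arm) stop("sequence shorter than two arms", call. = FALSE)
  ch <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "-")
  cch <- unname(comp[ch]); cch[is.na(cch)] <- "-"

  ## seeds: positions a < b with s[a..a+k-1] == revcomp(s[b-k+1..b])
  ## i.e. s[a+t] complements s[b-t] for t in 0..k-1
  rc <- paste(rev(cch), collapse = "")
  kmers_f <- substring(seq, 1:(n - k + 1), k:n)
  kmers_r <- substring(rc, 1:(n - k + 1), k:n)
  occ_r <- split(seq_along(kmers_r), kmers_r)
  hits <- list()
  for (a in seq_along(kmers_f)) {
    ps <- occ_r[[kmers_f[a]]]
    if (is.null(ps)) next
    for (p in ps) {
      b <- n - p + 1L            # s[b] pairs with s[a], b..b-k+1 descending
      if (b - k + 1L <= a + k - 1L + min_loop) next  # overlap / short loop
      hits[[length(hits) + 1L]] <- c(a = a, b = b)
    }
  }
  if (length(hits) == 0L) return(.empty_ir())
  H <- unique(do.call(rbind, hits))
  ## collapse seeds on the same diagonal (a + b constant)
  diag_ <- H[, "a"] + H[, "b"]
  reports <- list()
  for (dg in unique(diag_)) {
    sel <- H[diag_ == dg, , drop = FALSE]
    a0 <- min(sel[, "a"])
    b0 <- dg - a0
    ## extend: positions (a0 + t, b0 - t); greedy local max under +3/-4
    tmax <- floor((b0 - a0 - min_loop - 1) / 2)
    tt <- 0:tmax
    mm <- ch[a0 + tt] == cch[b0 - tt]
    sc <- ifelse(mm, 3, -4)
    cum <- cumsum(sc)
    best_t <- which.max(cum)
    ## also try trimming mismatching prefix: start at first match
    first <- which(mm)[1]
    if (is.na(first)) next
    if (first > 1) {
      tt2 <- first:length(tt)
      cum2 <- cumsum(sc[tt2])
      best2 <- which.max(cum2)
      if (max(cum2) > cum[best_t]) {
        a0 <- a0 + (first - 1L); b0 <- b0 - (first - 1L)
        mm <- mm[tt2]; sc <- sc[tt2]; cum <- cum2; best_t <- best2
      }
    }
    arm <- best_t
    score <- cum[best_t]
    if (arm < min_arm || score < min_score) next
    mism <- 100 * (1 - sum(mm[1:arm]) / arm)
    if (mism > max_mismatch_pct) next
    reports[[length(reports) + 1L]] <- data.frame(
      arm_length = arm, loop_length = (b0 - arm + 1L) - (a0 + arm - 1L) - 1L,
      start1 = a0, end1 = a0 + arm - 1L,
      start2 = b0 - arm + 1L, end2 = b0,
      matches = round(100 - mism, 1), score = score,
      stringsAsFactors = FALSE)
  }
  if (length(reports) == 0L) return(.empty_ir())
  tab <- unique(do.call(rbind, reports))
  tab <- tab[order(-tab$score), , drop = FALSE]
  ## non-overlapping by score (overlap measured on arm1 span)
  keep <- rep(TRUE, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(tab))) {
      if (j == i || !keep[j]) next
      ov1 <- min(tab$end1[i], tab$end1[j]) - max(tab$start1[i], tab$start1[j])
      ov2 <- min(tab$end2[i], tab$end2[j]) - max(tab$start2[i], tab$start2[j])
      if (ov1 >= 0 || ov2 >= 0) keep[j] <- FALSE
    }
  }
  tab <- tab[keep, , drop = FALSE]
  tab <- tab[order(tab$start1), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

.empty_ir <- function() {
  data.frame(arm_length = integer(0), loop_length = integer(0),
             start1 = integer(0), end1 = integer(0), start2 = integer(0),
             end2 = integer(0), matches = numeric(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Annotate control-region motif blocks
#'
#' Deterministic motif annotation: GA blocks (runs of G/A with at least
#' `ga_min` nt and two G), poly-T stretches (>= `polyt_min` T), and
#' `[TA(A)]n` blocks (>= `taa_min` consecutive TA/TAA units). GA blocks are
#' subtyped 5prime/3prime by position relative to the longest tandem
#' repeat (when one is present); hairpins are delegated to
#' [find_inverted_repeats()] and reported with kind `"hairpin"`.
#'
#' @param seq DNA string.
#' @param ga_min minimum GA-block length (default 6).
#' @param polyt_min minimum poly-T length (default 5).
#' @param taa_min minimum number of TA/TAA units (default 3).
#' @param repeats optional result of [find_tandem_repeats()] used for
#'   5prime/3prime subtyping (computed when `NULL` and the sequence is long
#'   enough; pass a zero-row data.frame to skip).
#' @param hairpins include hairpin blocks from [find_inverted_repeats()].
#' @return data.frame with columns `kind`, `start`, `end`, `subtype`.
#' @export
annotate_motifs <- function(seq, ga_min = 6L, polyt_min = 5L, taa_min = 3L,
                            repeats = NULL, hairpins = TRUE) {
  seq <- toupper(seq)
  n <- nchar(seq)
  out <- list()
  scan <- function(pattern, kind, filter = NULL) {
    m <- gregexpr(pattern, seq, perl = TRUE)[[1]]
    if (m[1] == -1) return()
    for (q in seq_along(m)) {
      s <- m[q]; e <- s + attr(m, "match.length")[q] - 1L
      if (!is.null(filter) && !filter(substr(seq, s, e))) next
      out[[length(out) + 1L]] <<- data.frame(kind = kind, start = s, end = e,
                                             subtype = "none",
                                             stringsAsFactors = FALSE)
    }
  }
  scan(sprintf("[GA]{%d,}", ga_min), "GA_block",
       filter = function(x) lengths(regmatches(x, gregexpr("G", x))) >= 2 &&
         grepl("A", x))
  scan(sprintf("T{%d,}", polyt_min), "polyT")
  scan(sprintf("(?:TAA|TA){%d,}", taa_min), "TAA_block")
  tab <- if (length(out)) do.call(rbind, out) else
    data.frame(kind = character(0), start = integer(0), end = integer(0),
               subtype = character(0), stringsAsFactors = FALSE)
  ## subtype GA blocks relative to the longest tandem repeat
  if (is.null(repeats) && n >= 24) repeats <- find_tandem_repeats(seq)
  if (!is.null(repeats) && nrow(repeats) > 0 && nrow(tab) > 0) {
    main <- repeats[which.max(repeats$score), ]
    ga <- tab$kind == "GA_block"
    tab$subtype[ga & tab$end < main$start] <- "5prime"
    tab$subtype[ga & tab$start > main$end] <- "3prime"
  }
  if (hairpins && n >= 24) {
    ir <- find_inverted_repeats(seq, min_arm = 10L)
    if (nrow(ir) > 0)
      tab <- rbind(tab, data.frame(kind = "hairpin", start = ir$start1,
                                   end = ir$end2, subtype = "none",
                                   stringsAsFactors = FALSE))
  }
  tab <- tab[order(tab$start), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
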