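# Independent reference implementations used to check the package's
# algorithms on small inputs. These deliberately use the most naive
# formulation available (full enumeration, direct scans).

# all circular inter-feature gaps of a genome, by direct coverage scan
brute_gaps <- function(genome) {
  L <- genome_length(genome)
  f <- genome$features
  covered <- logical(L)
  for (i in seq_len(nrow(f))) {
    if (isTRUE(f$wraps[i])) covered[c(f$start[i]:L, 1:f$end[i])] <- TRUE
    else covered[f$start[i]:f$end[i]] <- TRUE
  }
  # longest circular run of FALSE
  x <- c(covered, covered)
  best <- 0L
  run <- 0L
  for (i in seq_along(x)) {
    if (!x[i]) run <- run + 1L else run <- 0L
    if (run > best) best <- min(run, L)
  }
  best
}

# signed circular adjacency multiset, reflection-identified
brute_adjacencies <- function(ord) {
  n <- length(ord)
  flip <- function(x) paste0(ifelse(startsWith(x, "+"), "-", "+"),
                             sub("^[+-]", "", x))
  out <- character(0)
  for (i in seq_len(n)) {
    a <- ord[i]; b <- ord[if (i == n) 1L else i + 1L]
    fwd <- paste(a, b, sep = "|")
    rev <- paste(flip(b), flip(a), sep = "|")
    out <- c(out, min(fwd, rev))
  }
  out
}

brute_breakpoints <- function(o1, o2) {
  common <- intersect(sub("^[+-]", "", o1), sub("^[+-]", "", o2))
  o1 <- o1[sub("^[+-]", "", o1) %in% common]
  o2 <- o2[sub("^[+-]", "", o2) %in% common]
  sum(!brute_adjacencies(o1) %in% brute_adjacencies(o2))
}

# canonical form by brute force: all rotations of the order and of its
# reflection; the unique one starting at +cox1
brute_canonical <- function(ord) {
  flip <- function(x) paste0(ifelse(startsWith(x, "+"), "-", "+"),
                             sub("^[+-]", "", x))
  rotations <- function(x) lapply(seq_along(x), function(i)
    c(x[i:length(x)], x[seq_len(i - 1)])[seq_along(x)])
  cands <- c(rotations(ord), rotations(rev(flip(ord))))
  hits <- Filter(function(x) x[1] == "+cox1", cands)
  stopifnot(length(hits) >= 1)
  hits[[1]]
}

# pathway-enumeration oracle for NG86 substitution counts between two
# codons under the invertebrate mitochondrial code
oracle_path_counts <- function(c1, c2) {
  code <- Biostrings::getGeneticCode("5")
  names(code) <- chartr("U", "T", names(code))
  d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(d) == 0) return(c(syn = 0, nonsyn = 0))
  perms <- if (length(d) == 1) list(d) else {
    ps <- list()
    rec <- function(prefix, rest) {
      if (!length(rest)) { ps[[length(ps) + 1L]] <<- prefix; return() }
      for (i in seq_along(rest)) rec(c(prefix, rest[i]), rest[-i])
    }
    rec(integer(0), d)
    ps
  }
  walk <- function(order_) {
    cur <- strsplit(c1, "")[[1]]; tgt <- strsplit(c2, "")[[1]]
    s <- 0; ns <- 0
    for (p in order_) {
      from <- code[[paste(cur, collapse = "")]]
      cur[p] <- tgt[p]
      to <- code[[paste(cur, collapse = "")]]
      if (to == "*" || from == "*") return(NULL)
      if (from == to) s <- s + 1 else ns <- ns + 1
    }
    c(s, ns)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk))
  if (!length(res)) return(NULL)  # all pathways blocked
  m <- do.call(rbind, res)
  c(syn = mean(m[, 1]), nonsyn = mean(m[, 2]))
}

# two-sided Fisher p by full enumeration of the hypergeometric support
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(xs, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# SSR oracle: regex with backreferences, maximal matches
oracle_ssrs <- function(seq, min_copies = c(`1` = 12, `2` = 6, `3` = 4,
                                            `4` = 3, `5` = 3, `6` = 3)) {
  out <- list()
  for (u in 1:6) {
    thr <- min_copies[[as.character(u)]]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, thr - 1)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1) next
    for (q in seq_along(m)) {
      s <- m[q]; len <- attr(m, "match.length")[q]
      unit <- substr(seq, s, s + u - 1)
      # primitive units only
      prim <- !any(vapply(seq_len(u - 1), function(p)
        u %% p == 0 && unit == strrep(substr(unit, 1, p), u / p), logical(1)))
      if (!prim) next
      out[[length(out) + 1L]] <- data.frame(
        unit = unit, copies = len %/% u, start = s,
        end = s + (len %/% u) * u - 1, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  tab <- do.call(rbind, out)
  tab[order(tab$start), ]
}

random_signed_order <- function(n_genes, with_cox1 = TRUE) {
  genes <- if (with_cox1) c("cox1", paste0("g", seq_len(n_genes - 1)))
           else paste0("g", seq_len(n_genes))
  paste0(sample(c("+", "-"), n_genes, replace = TRUE), sample(genes))
}
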