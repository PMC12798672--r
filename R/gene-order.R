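## gene_order: canonicalized signed circular permutations over the 37-gene
## vocabulary, arrangement typing, diffs against the pancrustacean ground
## pattern, and breakpoint distances.
##
## A signed gene order is a character vector like c("+cox1", "-trnQ", ...).
## Canonical form starts at +cox1; if cox1 lies on the minus strand the
## whole order is reflected (reversed and sign-flipped) first, so circular
## equality reduces to string equality.

#' Construct a GeneOrder
#'
#' @param order character vector of signed canonical symbols
#'   (`"+cox1"`, `"-trnQ"`, ...).
#' @param accession identifier.
#' @param include_cr whether `CR` is part of the order.
#' @return object of class `GeneOrder`.
#' @export
gene_order <- function(order, accession = NA_character_, include_cr = FALSE) {
  stopifnot(is.character(order), length(order) >= 1)
  if (!all(grepl("^[+-]", order)))
    stop("every element must carry a +/- sign prefix", call. = FALSE)
  structure(list(accession = accession, order = order,
                 include_cr = include_cr), class = "GeneOrder")
}

#' @export
print.GeneOrder <- function(x, ...) {
  cat("GeneOrder", x$accession, "\n ", paste(x$order, collapse = ","), "\n")
  invisible(x)
}

#' Signed gene order of an annotated genome
#'
#' Features are taken in plus-strand start order (circular start at the
#' first feature); sign encodes strand. CR is excluded by default.
#'
#' @param genome a `MitoGenome`.
#' @param include_cr keep the CR symbol in the order.
#' @return a [gene_order()] object (not yet canonicalized).
#' @export
gene_order_from_genome <- function(genome, include_cr = FALSE) {
  f <- genome$features[order(genome$features$start), ]
  if (!include_cr) f <- f[f$kind != "CR", , drop = FALSE]
  gene_order(paste0(ifelse(f$strand == "+", "+", "-"), f$name),
             accession = genome$accession, include_cr = include_cr)
}

.sym <- function(order) sub("^[+-]", "", order)
.sgn <- function(order) ifelse(startsWith(order, "+"), 1L, -1L)
.flip <- function(order) paste0(ifelse(startsWith(order, "+"), "-", "+"),
                                .sym(order))

#' Canonicalize a circular signed gene order
#'
#' Rotates the order so `+cox1` is first; if `cox1` is on the minus strand
#' the order is reflected (reversed with all signs flipped) before
#' rotation. Canonicalization is idempotent.
#'
#' @param x a `GeneOrder` (or bare signed character vector).
#' @return canonicalized `GeneOrder`.
#' @export
canonicalize <- function(x) {
  ord <- if (inherits(x, "GeneOrder")) x$order else x
  i <- which(.sym(ord) == "cox1")
  if (length(i) == 0L)
    stop("canonicalization error: order lacks cox1", call. = FALSE)
  i <- i[1]
  if (.sgn(ord)[i] < 0) {
    ord <- rev(.flip(ord))
    i <- which(.sym(ord) == "cox1")[1]
  }
  if (i > 1L) ord <- c(ord[i:length(ord)], ord[seq_len(i - 1L)])
  if (inherits(x, "GeneOrder"))
    gene_order(ord, accession = x$accession, include_cr = x$include_cr)
  else ord
}

#' Partition gene orders into arrangement types
#'
#' Equivalence classes under exact equality of canonicalized orders.
#' Type ids are assigned in first-seen order after sorting input by
#' accession (deterministic tie-break).
#'
#' @param orders list of `GeneOrder` objects over the same vocabulary.
#' @return list of `ArrangementType` lists: `type_id`, `members`
#'   (accessions), `representative` (canonical `GeneOrder`).
#' @export
partition_types <- function(orders) {
  stopifnot(length(orders) >= 1)
  orders <- lapply(orders, canonicalize)
  acc <- vapply(orders, function(o) as.character(o$accession), character(1))
  ord_idx <- order(acc, na.last = TRUE)
  orders <- orders[ord_idx]
  acc <- acc[ord_idx]
  keys <- vapply(orders, function(o) paste(o$order, collapse = ","),
                 character(1))
  uk <- unique(keys)
  lapply(seq_along(uk), function(i) {
    m <- which(keys == uk[i])
    structure(list(type_id = i, members = acc[m],
                   representative = orders[[m[1]]]),
              class = "ArrangementType")
  })
}

## signed circular adjacency set; (a,b) is identified with (-b,-a)
.adjacencies <- function(ord) {
  n <- length(ord)
  nxt <- c(ord[-1], ord[1])
  fwd <- paste(ord, nxt, sep = "|")
  rev <- paste(.flip(nxt), .flip(ord), sep = "|")
  ifelse(fwd < rev, fwd, rev)  # canonical representative of each adjacency
}

.restrict <- function(ord, genes) ord[.sym(ord) %in% genes]

#' Breakpoint distance between two gene orders
#'
#' Number of signed circular adjacencies present in `o1` but absent from
#' `o2`, after restricting both orders to their common genes. An adjacency
#' `(a, b)` is identified with its reading on the opposite strand
#' `(-b, -a)`. Zero iff the canonical orders are equal; symmetric for equal
#' gene sets.
#'
#' @param o1,o2 `GeneOrder` objects (or signed character vectors).
#' @return non-negative integer.
#' @export
breakpoint_distance <- function(o1, o2) {
  a <- if (inherits(o1, "GeneOrder")) o1$order else o1
  b <- if (inherits(o2, "GeneOrder")) o2$order else o2
  common <- intersect(.sym(a), .sym(b))
  if (length(common) < 2) return(0L)
  a <- .restrict(a, common); b <- .restrict(b, common)
  sum(!.adjacencies(a) %in% .adjacencies(b))
}

#' Diff a gene order against a reference
#'
#' Both orders are restricted to their shared genes. A shared gene is
#' reported as *translocated* when both of its reference adjacencies are
#' broken (its two neighbours differ from the reference), and *inverted*
#' when its unsigned neighbourhood is conserved but its own sign is flipped.
#' Maximal runs of conserved signed adjacencies are returned as
#' `conserved_blocks`.
#'
#' @param order,reference `GeneOrder` objects.
#' @return list of class `RearrangementDiff`: `translocated`, `inverted`,
#'   `conserved_blocks` (list of character vectors of canonical symbols).
#' @export
diff_vs_reference <- function(order, reference) {
  a <- if (inherits(order, "GeneOrder")) order$order else order
  r <- if (inherits(reference, "GeneOrder")) reference$order else reference
  common <- intersect(.sym(a), .sym(r))
  if (length(common) < 2)
    stop("orders share fewer than 2 genes", call. = FALSE)
  a <- canonicalize(.restrict(a, common))
  r <- canonicalize(.restrict(r, common))

  adj_r_set <- .adjacencies(r)
  n <- length(a)
  sy_a <- .sym(a); sy_r <- .sym(r)
  adj_a <- .adjacencies(a)                  # adjacency i is (a[i], a[i+1])
  kept <- adj_a %in% adj_r_set
  ## incident adjacencies of gene at position i: left = i-1 (circular), right = i
  left_kept <- kept[c(n, seq_len(n - 1L))]
  right_kept <- kept

  translocated <- character(0); inverted <- character(0)
  prev_a <- sy_a[c(n, seq_len(n - 1L))]; next_a <- sy_a[c(seq(2L, n), 1L)]
  nr_ <- length(r)
  prev_r <- setNames(sy_r[c(nr_, seq_len(nr_ - 1L))], sy_r)
  next_r <- setNames(sy_r[c(seq(2L, nr_), 1L)], sy_r)
  sgn_r <- setNames(.sgn(r), sy_r)
  for (i in seq_len(n)) {
    if (left_kept[i] || right_kept[i]) next  # at most one adjacency broken
    g <- sy_a[i]
    same_neigh <- setequal(c(prev_a[i], next_a[i]),
                           c(prev_r[[g]], next_r[[g]]))
    if (same_neigh && .sgn(a)[i] != sgn_r[[g]]) {
      inverted <- c(inverted, g)
    } else if (!same_neigh) {
      translocated <- c(translocated, g)
    }
    ## same unsigned neighbours, same sign: the gene itself did not move
    ## (its context was rearranged around it) - not listed
  }

  ## conserved blocks: maximal runs of shared signed adjacencies in `a`
  adj_r <- .adjacencies(r)
  n <- length(a)
  nxt <- c(a[-1], a[1])
  shared <- .adjacencies(a) %in% adj_r
  blocks <- list()
  if (any(shared)) {
    ## walk circularly; a block is a maximal chain of shared adjacencies
    start_pts <- which(shared & !c(shared[n], shared[-n]))
    if (length(start_pts) == 0L) {
      blocks <- list(.sym(a))  # every adjacency shared: whole circle
    } else {
      for (s in start_pts) {
        genes <- .sym(a)[s]
        i <- s
        while (shared[i]) {
          i2 <- if (i == n) 1L else i + 1L
          genes <- c(genes, .sym(a)[i2])
          i <- i2
          if (i == s) break
        }
        blocks[[length(blocks) + 1L]] <- genes
      }
    }
  }
  structure(list(translocated = translocated, inverted = inverted,
                 conserved_blocks = blocks), class = "RearrangementDiff")
}

#' @export
print.RearrangementDiff <- function(x, ...) {
  cat("RearrangementDiff\n")
  cat("  translocated:", if (length(x$translocated))
    paste(x$translocated, collapse = ", ") else "(none)", "\n")
  cat("  inverted:    ", if (length(x$inverted))
    paste(x$inverted, collapse = ", ") else "(none)", "\n")
  cat("  conserved blocks:", length(x$conserved_blocks), "\n")
  invisible(x)
}

#' Reference gene orders (pancrustacean ground pattern)
#'
#' `"canonical37"` is the complete 37-gene pancrustacean ground pattern
#' (the arrangement of *Drosophila yakuba*, shared by most crustaceans)
#' with strands. `"paper"` is the 32-gene anchor string as commonly printed
#' in the comparative literature, which omits trnG, trnA, trnV, rrnL and
#' rrnS; strands are assigned from the canonical pattern since anchor
#' strings carry no strand information.
#'
#' @param which `"canonical37"` (default) or `"paper"`.
#' @return a canonical `GeneOrder`.
#' @export
ground_pattern <- function(which = c("canonical37", "paper")) {
  which <- match.arg(which)
  canonical <- c("+cox1", "+trnL2", "+cox2", "+trnK", "+trnD", "+atp8",
                 "+atp6", "+cox3", "+trnG", "+nad3", "+trnA", "+trnR",
                 "+trnN", "+trnS1", "+trnE", "-trnF", "-nad5", "-trnH",
                 "-nad4", "-nad4L", "+trnT", "-trnP", "+nad6", "+cob",
                 "+trnS2", "-nad1", "-trnL1", "-rrnL", "-trnV", "-rrnS",
                 "+trnI", "-trnQ", "+trnM", "+nad2", "+trnW", "-trnC",
                 "-trnY")
  if (which == "canonical37")
    return(canonicalize(gene_order(canonical, accession = "canonical37")))
  paper_syms <- c("cox1", "trnL1", "trnL2", "cox2", "trnK", "nad3", "trnM",
                  "trnI", "nad2", "trnD", "atp8", "atp6", "cox3", "trnR",
                  "trnN", "trnS1", "trnE", "trnF", "nad5", "trnH", "nad4",
                  "nad4L", "trnT", "nad6", "cob", "trnS2", "trnP", "nad1",
                  "trnW", "trnQ", "trnC", "trnY")
  sgn <- setNames(ifelse(startsWith(canonical, "+"), "+", "-"),
                  .sym(canonical))
  canonicalize(gene_order(paste0(sgn[paper_syms], paper_syms),
                          accession = "paper"))
}

#' Write gene orders and arrangement types as TSV
#'
#' @param orders list of `GeneOrder` objects.
#' @param types result of [partition_types()] (computed if `NULL`).
#' @param order_path,type_path output TSV paths (skipped when `NULL`).
#' @return the types, invisibly.
#' @export
write_gene_order_tables <- function(orders, types = NULL,
                                    order_path = NULL, type_path = NULL) {
  if (is.null(types)) types <- partition_types(orders)
  if (!is.null(order_path)) {
    tab <- data.frame(
      accession = vapply(orders, function(o) as.character(o$accession),
                         character(1)),
      order = vapply(orders, function(o) paste(o$order, collapse = ","),
                     character(1)), stringsAsFactors = FALSE)
    write.table(tab, order_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(type_path)) {
    tab <- data.frame(
      type_id = vapply(types, `[[`, integer(1), "type_id"),
      n_members = vapply(types, function(t) length(t$members), integer(1)),
      members = vapply(types, function(t) paste(t$members, collapse = ";"),
                       character(1)),
      representative = vapply(types, function(t)
        paste(t$representative$order, collapse = ","), character(1)),
      stringsAsFactors = FALSE)
    write.table(tab, type_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(types)
}

#' Read a gene-order TSV written by [write_gene_order_tables()]
#' @param path TSV with columns `accession`, `order`.
#' @return list of `GeneOrder` objects.
#' @export
read_gene_order_table <- function(path) {
  tab <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i)
    gene_order(strsplit(tab$order[i], ",")[[1]], accession = tab$accession[i]))
}
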