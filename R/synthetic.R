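## synthetic_data: deterministic generators for mitogenomes, control
## regions and codon pairs with recorded ground truth. Every generator is
## a pure function of its spec (including the integer seed): R's
## Mersenne-Twister stream is seeded locally and the caller's RNG state is
## restored on exit.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

.rand_dna <- function(n, composition) {
  if (n <= 0) return("")
  paste(sample(names(composition), n, replace = TRUE, prob = composition),
        collapse = "")
}

.DEFAULT_COMPOSITION <- c(A = 0.317, C = 0.098, G = 0.167, T = 0.418)

## ---- control region ---------------------------------------------------------

#' Specification for a synthetic control region
#'
#' Defaults emulate the conserved anomuran control-region architecture: a
#' ~47 bp motif repeated ~3.6 times, flanking GA blocks, poly-T stretches,
#' `[TA(A)]n` blocks and hairpin stems embedded in an AT-rich background.
#'
#' @param length region length in bp.
#' @param repeat_period,repeat_copies,repeat_mutation_rate tandem-repeat
#'   truth: motif length (bp), copy number, per-base point-mutation rate
#'   applied per copy.
#' @param n_polyT,n_GA_blocks,n_TAA_blocks numbers of planted motif blocks.
#' @param hairpin_stems list of `c(arm_bp, loop_bp)` pairs.
#' @param composition background base frequencies (must sum to 1).
#' @param seed integer seed.
#' @return list of class `CRSpec`.
#' @export
cr_spec <- function(length = 1300L, repeat_period = 47L, repeat_copies = 3.6,
                    repeat_mutation_rate = 0.05, n_polyT = 2L,
                    n_GA_blocks = 3L, n_TAA_blocks = 2L,
                    hairpin_stems = list(c(12L, 5L)),
                    composition = c(A = 0.33, C = 0.12, G = 0.16, T = 0.39),
                    seed = 1L) {
  stopifnot(abs(sum(composition) - 1) < 1e-8, repeat_copies >= 0,
            repeat_period >= 1)
  structure(list(length = as.integer(length),
                 repeat_period = as.integer(repeat_period),
                 repeat_copies = repeat_copies,
                 repeat_mutation_rate = repeat_mutation_rate,
                 n_polyT = n_polyT, n_GA_blocks = n_GA_blocks,
                 n_TAA_blocks = n_TAA_blocks,
                 hairpin_stems = hairpin_stems,
                 composition = composition, seed = as.integer(seed)),
            class = "CRSpec")
}

.mutate_bases <- function(s, rate) {
  if (rate <= 0 || nchar(s) == 0) return(s)
  ch <- strsplit(s, "")[[1]]
  hit <- runif(length(ch)) < rate
  if (any(hit))
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste(ch, collapse = "")
}

#' Generate a synthetic control region with recorded truth
#'
#' Background sequence at the target composition; the tandem repeat is a
#' random period-length motif copied `repeat_copies` times with per-copy
#' point mutations; motif blocks and hairpins are planted left-to-right at
#' randomized non-overlapping positions, all coordinates recorded.
#'
#' @param spec a [cr_spec()].
#' @return list with `sequence` (DNA string of length `spec$length`) and
#'   `truth` (repeat coordinates/period/copies/consensus, motif and hairpin
#'   coordinates, seed).
#' @export
generate_control_region <- function(spec = cr_spec()) {
  stopifnot(inherits(spec, "CRSpec"))
  with_seed(spec$seed, {
    L <- spec$length
    ## build elements (sequence strings + kinds), repeat placed centrally
    elements <- list()
    add <- function(kind, s, extra = NULL)
      elements[[length(elements) + 1L]] <<-
        c(list(kind = kind, seq = s), extra)
    motif <- .rand_dna(spec$repeat_period, spec$composition)
    n_full <- floor(spec$repeat_copies)
    frac <- spec$repeat_copies - n_full
    copies <- character(0)
    for (i in seq_len(n_full))
      copies <- c(copies, .mutate_bases(motif, spec$repeat_mutation_rate))
    if (frac > 0) {
      part <- substr(motif, 1, round(frac * spec$repeat_period))
      copies <- c(copies, .mutate_bases(part, spec$repeat_mutation_rate))
    }
    rep_seq <- paste(copies, collapse = "")
    for (i in seq_len(spec$n_GA_blocks)) {
      len <- sample(8:14, 1)
      repeat {
        s <- paste(sample(c("G", "A"), len, replace = TRUE,
                          prob = c(0.45, 0.55)), collapse = "")
        if (lengths(regmatches(s, gregexpr("G", s))) >= 2 && grepl("A", s))
          break
      }
      add("GA_block", s)
    }
    half <- ceiling(spec$n_GA_blocks / 2)  # some 5' of the repeat, rest 3'
    for (i in seq_len(spec$n_polyT))
      add("polyT", strrep("T", sample(6:10, 1)))
    for (i in seq_len(spec$n_TAA_blocks))
      add("TAA_block", paste(sample(c("TA", "TAA"), sample(3:5, 1),
                                    replace = TRUE), collapse = ""))
    for (hp in spec$hairpin_stems) {
      arm <- paste(sample(c("G", "C", "A", "T"), hp[1], replace = TRUE,
                          prob = c(0.35, 0.35, 0.15, 0.15)), collapse = "")
      add("hairpin", paste0(arm, .rand_dna(hp[2], spec$composition),
                            revcomp(arm)),
          list(arm = hp[1], loop = hp[2]))
    }
    ## order: GA 5' half, polyT/TAA interleaved, repeat, rest
    kinds <- vapply(elements, `[[`, character(1), "kind")
    ga_idx <- which(kinds == "GA_block")
    other_idx <- setdiff(seq_along(elements), ga_idx)
    order_idx <- c(ga_idx[seq_len(min(half, length(ga_idx)))],
                   other_idx[seq_along(other_idx) %% 2 == 1])
    post_idx <- setdiff(seq_along(elements), c(order_idx))
    layout <- list()
    for (i in order_idx) layout[[length(layout) + 1L]] <- elements[[i]]
    layout[[length(layout) + 1L]] <- list(kind = "repeat", seq = rep_seq,
                                          period = spec$repeat_period,
                                          copies = spec$repeat_copies,
                                          consensus = motif)
    for (i in post_idx) layout[[length(layout) + 1L]] <- elements[[i]]

    elem_len <- sum(vapply(layout, function(e) nchar(e$seq), numeric(1)))
    slack <- L - elem_len
    if (slack < length(layout) + 1)
      stop("spec error: planted elements exceed region length", call. = FALSE)
    ## randomized gaps summing to slack
    w <- runif(length(layout) + 1)
    gaps <- floor(slack * w / sum(w))
    gaps[length(gaps)] <- slack - sum(gaps[-length(gaps)])
    parts <- character(0)
    truth_rows <- list()
    pos <- 0L
    for (k in seq_along(layout)) {
      g <- gaps[k]
      parts <- c(parts, .rand_dna(g, spec$composition))
      pos <- pos + g
      e <- layout[[k]]
      s <- pos + 1L
      parts <- c(parts, e$seq)
      pos <- pos + nchar(e$seq)
      truth_rows[[k]] <- data.frame(kind = e$kind, start = s, end = pos,
                                    stringsAsFactors = FALSE)
    }
    parts <- c(parts, .rand_dna(gaps[length(gaps)], spec$composition))
    sequence <- paste(parts, collapse = "")
    truth_tab <- do.call(rbind, truth_rows)
    rep_row <- truth_tab[truth_tab$kind == "repeat", ]
    truth <- list(
      elements = truth_tab,
      repeat_ = list(start = rep_row$start, end = rep_row$end,
                     period = spec$repeat_period,
                     copies = spec$repeat_copies, consensus = motif),
      hairpins = truth_tab[truth_tab$kind == "hairpin", ],
      seed = spec$seed)
    list(sequence = sequence, truth = truth)
  })
}

## ---- whole genomes ----------------------------------------------------------

.PCG_LEN <- c(cox1 = 1536, cox2 = 684, cox3 = 786, cob = 1134, nad1 = 936,
              nad2 = 1002, nad3 = 351, nad4 = 1338, nad4L = 297,
              nad5 = 1716, nad6 = 519, atp6 = 675, atp8 = 159)
.RRNA_LEN <- c(rrnL = 1300, rrnS = 800)

#' Specification for a synthetic mitogenome
#'
#' @param base_order a `GeneOrder` over the 37-gene vocabulary (default the
#'   canonical pancrustacean ground pattern); the control region is placed
#'   after `cr_after` (default rrnS, its canonical location).
#' @param rearrangements list of events applied to `base_order`:
#'   `list(type = "transposition", gene, after)` moves a gene after another
#'   (`after = NULL` moves it to the front), `list(type = "inversion",
#'   genes)` reverses and strand-flips a contiguous block.
#' @param composition plus-strand base frequencies.
#' @param cr_spec_ control-region spec ([cr_spec()]); its seed is derived
#'   from `seed` when `NULL`.
#' @param annotate_cr annotate the control region explicitly (default
#'   `FALSE`: the CR is left as the longest unannotated gap).
#' @param accession,taxon identifiers.
#' @param seed integer seed.
#' @return list of class `SyntheticGenomeSpec`.
#' @export
genome_spec <- function(base_order = ground_pattern("canonical37"),
                        rearrangements = list(),
                        composition = .DEFAULT_COMPOSITION,
                        cr_spec_ = NULL, annotate_cr = FALSE,
                        accession = "SYN000001", taxon = "Synthetica exempli",
                        cr_after = "rrnS", seed = 1L) {
  structure(list(base_order = base_order, rearrangements = rearrangements,
                 composition = composition, cr_spec_ = cr_spec_,
                 annotate_cr = annotate_cr, accession = accession,
                 taxon = taxon, cr_after = cr_after, seed = as.integer(seed)),
            class = "SyntheticGenomeSpec")
}

.apply_rearrangements <- function(order, events) {
  touched <- character(0)
  for (ev in events) {
    if (ev$type == "transposition") {
      i <- which(.sym(order) == ev$gene)
      if (length(i) != 1)
        stop("spec error: transposition target ", ev$gene, " not in order",
             call. = FALSE)
      g <- order[i]
      order <- order[-i]
      j <- if (is.null(ev$after)) 0L else which(.sym(order) == ev$after)
      if (length(j) != 1)
        stop("spec error: anchor ", ev$after, " not in order", call. = FALSE)
      order <- append(order, g, after = j)
      touched <- c(touched, ev$gene)
    } else if (ev$type == "inversion") {
      idx <- match(ev$genes, .sym(order))
      if (any(is.na(idx)) || !all(diff(sort(idx)) == 1))
        stop("spec error: inversion block must be contiguous", call. = FALSE)
      idx <- sort(idx)
      order[idx] <- rev(.flip(order[idx]))
      touched <- c(touched, ev$genes)
    } else stop("unknown rearrangement type: ", ev$type, call. = FALSE)
  }
  list(order = order, touched = unique(touched))
}

.random_cds <- function(n_codons, composition) {
  sense <- sense_codons()
  sense <- sense[!sense %in% c("ATG")]
  ## weight codons by the product of target base frequencies
  w <- vapply(sense, function(cod) {
    prod(composition[strsplit(cod, "")[[1]]])
  }, numeric(1))
  body <- sample(sense, n_codons - 2L, replace = TRUE, prob = w)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

#' Generate an annotated synthetic mitogenome with recorded truth
#'
#' Genes are drawn as random ORFs (PCGs, invertebrate mito code, ATG start,
#' TAA stop), random 60-75 nt segments (tRNAs) and longer random segments
#' (rRNAs); the control region comes from [generate_control_region()] and
#' is left unannotated by default so the longest-gap locator can be
#' exercised. Identical seeds give byte-identical output.
#'
#' @param spec a [genome_spec()].
#' @return list with `genome` (a `MitoGenome`) and `truth` (realized signed
#'   gene order, rearranged genes, CR span and truth, seed).
#' @export
generate_genome <- function(spec = genome_spec()) {
  stopifnot(inherits(spec, "SyntheticGenomeSpec"))
  with_seed(spec$seed, {
    base <- canonicalize(spec$base_order)
    rr <- .apply_rearrangements(base$order, spec$rearrangements)
    ord <- rr$order
    crs <- spec$cr_spec_
    if (is.null(crs)) crs <- cr_spec(seed = spec$seed + 101L)
    cr <- generate_control_region(crs)

    comp <- spec$composition
    rows <- list(); parts <- character(0); pos <- 0L
    cr_span <- NULL
    emit <- function(name, s, strand, kind, annotate = TRUE) {
      spacer <- .rand_dna(sample(2:8, 1), comp)
      parts <<- c(parts, spacer)
      pos <<- pos + nchar(spacer)
      start <- pos + 1L
      if (strand == "-") s <- revcomp(s)
      parts <<- c(parts, s)
      pos <<- pos + nchar(s)
      if (annotate)
        rows[[length(rows) + 1L]] <<-
          data.frame(name = name, start = start, end = pos, strand = strand,
                     kind = kind, wraps = FALSE, stringsAsFactors = FALSE)
      c(start, pos)
    }
    for (g in ord) {
      nm <- .sym(g); strand <- if (startsWith(g, "+")) "+" else "-"
      kind <- gene_kind(nm)
      s <- switch(kind,
        PCG = .random_cds(.PCG_LEN[[nm]] / 3, comp),
        tRNA = .rand_dna(sample(60:75, 1), comp),
        rRNA = .rand_dna(.RRNA_LEN[[nm]], comp),
        stop("unexpected kind for ", nm))
      emit(nm, s, strand, kind)
      if (nm == spec$cr_after) {
        cr_span <- emit("CR", cr$sequence, "+", "CR",
                        annotate = spec$annotate_cr)
      }
    }
    if (is.null(cr_span))
      cr_span <- emit("CR", cr$sequence, "+", "CR",
                      annotate = spec$annotate_cr)
    sequence <- paste(parts, collapse = "")
    feats <- do.call(rbind, rows)
    genome <- mito_genome(spec$accession, sequence, feats,
                          taxon = spec$taxon)
    truth <- list(gene_order = ord, rearranged = rr$touched,
                  cr_start = cr_span[1], cr_end = cr_span[2],
                  cr_truth = cr$truth, seed = spec$seed)
    list(genome = genome, truth = truth)
  })
}

## ---- codon pair evolution ---------------------------------------------------

#' Specification for an evolved codon pair
#'
#' @param n_codons number of sense codons (>= 10).
#' @param omega true Ka/Ks (nonsynonymous acceptance rate).
#' @param kappa transition/transversion rate ratio. Default 1, matching the
#'   equal-rate assumption of the NG86 estimator this harness validates;
#'   raise it for sensitivity analyses.
#' @param t expected synonymous divergence between the two sequences
#'   (synonymous substitutions per synonymous site, split evenly over the
#'   two branches).
#' @param seed integer seed.
#' @return list of class `CodonPairSpec`.
#' @export
codon_pair_spec <- function(n_codons = 500L, omega = 0.2, kappa = 1,
                            t = 0.3, seed = 1L) {
  stopifnot(n_codons >= 10, omega >= 0, kappa > 0, t >= 0)
  structure(list(n_codons = as.integer(n_codons), omega = omega,
                 kappa = kappa, t = t, seed = as.integer(seed)),
            class = "CodonPairSpec")
}

## change table: for each sense codon, the 9 single-nucleotide neighbours
.codon_changes <- function() {
  if (!is.null(.kaks_env$changes)) return(.kaks_env$changes)
  code <- mito_genetic_code()
  bases <- c("A", "C", "G", "T")
  is_ts <- function(a, b) (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
  out <- list()
  for (cod in sense_codons()) {
    cs <- strsplit(cod, "")[[1]]
    rows <- list()
    for (p in 1:3) for (b in setdiff(bases, cs[p])) {
      cs2 <- cs; cs2[p] <- b
      cod2 <- paste(cs2, collapse = "")
      if (code[[cod2]] == "*") next
      rows[[length(rows) + 1L]] <- data.frame(
        to = cod2, ts = is_ts(cs[p], b), syn = code[[cod2]] == code[[cod]],
        stringsAsFactors = FALSE)
    }
    out[[cod]] <- do.call(rbind, rows)
  }
  .kaks_env$changes <- out
  out
}

.evolve_branch <- function(codons, tau, omega, kappa, changes) {
  rate_of <- function(cod)
    sum(ifelse(changes[[cod]]$ts, kappa, 1) *
          ifelse(changes[[cod]]$syn, 1, omega))
  rates <- vapply(codons, rate_of, numeric(1))
  time <- 0; n_syn <- 0L; n_nonsyn <- 0L
  repeat {
    R <- sum(rates)
    if (R <= 0) break
    time <- time + stats::rexp(1, R)
    if (time > tau) break
    i <- sample.int(length(codons), 1, prob = rates)
    ch <- changes[[codons[i]]]
    w <- ifelse(ch$ts, kappa, 1) * ifelse(ch$syn, 1, omega)
    j <- sample.int(nrow(ch), 1, prob = w)
    if (ch$syn[j]) n_syn <- n_syn + 1L else n_nonsyn <- n_nonsyn + 1L
    codons[i] <- ch$to[j]
    rates[i] <- rate_of(codons[i])
  }
  list(codons = codons, n_syn = n_syn, n_nonsyn = n_nonsyn)
}

#' Evolve a homologous codon-sequence pair at a known omega
#'
#' An ancestor of random sense codons is evolved along two independent
#' branches by a continuous-time codon process: single-nucleotide proposals
#' with `kappa` transition bias, synonymous changes accepted at rate 1,
#' nonsynonymous at rate `omega`, stop-generating changes rejected. Branch
#' durations are scaled so the expected synonymous divergence between the
#' two sequences (synonymous substitutions per NG86 synonymous site at the
#' ancestor) equals `t`. Realized substitution counts are recorded.
#'
#' @param spec a [codon_pair_spec()].
#' @return list with `cds1`, `cds2` (DNA strings) and `truth`
#'   (`omega`, `kappa`, `t`, per-branch realized syn/nonsyn counts,
#'   ancestor sequence, seed).
#' @export
evolve_codon_pair <- function(spec = codon_pair_spec()) {
  stopifnot(inherits(spec, "CodonPairSpec"))
  changes <- .codon_changes()
  with_seed(spec$seed, {
    anc <- sample(sense_codons(), spec$n_codons, replace = TRUE)
    ## time scale: expected syn substitutions per syn site = 1 per unit time
    syn_flux <- sum(vapply(anc, function(cod)
      sum(ifelse(changes[[cod]]$ts, spec$kappa, 1) * changes[[cod]]$syn),
      numeric(1)))
    sites <- .codon_sites()
    L_S0 <- sum(sites[anc])
    tau <- if (syn_flux > 0) (spec$t / 2) * L_S0 / syn_flux else 0
    b1 <- .evolve_branch(anc, tau, spec$omega, spec$kappa, changes)
    b2 <- .evolve_branch(anc, tau, spec$omega, spec$kappa, changes)
    list(cds1 = paste(b1$codons, collapse = ""),
         cds2 = paste(b2$codons, collapse = ""),
         truth = list(omega = spec$omega, kappa = spec$kappa, t = spec$t,
                      n_codons = spec$n_codons,
                      branch1 = c(syn = b1$n_syn, nonsyn = b1$n_nonsyn),
                      branch2 = c(syn = b2$n_syn, nonsyn = b2$n_nonsyn),
                      ancestor = paste(anc, collapse = ""),
                      seed = spec$seed))
  })
}
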