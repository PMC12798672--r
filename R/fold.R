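## Minimum-free-energy secondary structure (control regions, tRNAs).
##
## The paper-style procedure folds the DNA control region as RNA (T read as
## U) with a nearest-neighbour energy model; a Turner-style parameter table
## is packaged as dH/dS-equivalent pairs so that the free energy can be
## rescaled to any temperature (default 27 degC). The DP lives in
## src/fold.cpp; `fold_enumerate()` is an independent brute-force reference
## that evaluates every valid structure of a short sequence under the same
## parameter table.

.fold_env <- new.env(parent = emptyenv())

.PAIR_TYPES <- c("AU", "UA", "GC", "CG", "GU", "UG")

.GAS_R <- 0.0019872  # kcal / (mol K)
.T37 <- 310.15

#' Folding parameter table at a given temperature
#'
#' Loads the packaged nearest-neighbour table (stack dG37/dH pairs; loop
#' penalties stored as dG37 and treated as purely entropic) and rescales it
#' to the requested temperature via dG(T) = dH - T (dH - dG37) / 310.15.
#' GU/UG-containing stacks, absent from the packaged table, receive generic
#' wobble energies (one wobble pair: -1.3 kcal/mol at 37 degC, dH -8.0;
#' two: -0.5, dH -5.0), symmetric by construction.
#'
#' @param temperature temperature in degrees Celsius (default 27, the
#'   paper-style setting).
#' @return list with components `stack` (6x6 matrix over pair types
#'   AU,UA,GC,CG,GU,UG), `hairpin`, `bulge`, `internal` (penalty vectors by
#'   unpaired size, 1..30), `hp_ext` (logarithmic hairpin extrapolation
#'   coefficient 1.75*R*T), `Ma`, `Mb`, `Mc` (multibranch affine terms),
#'   `maxloop`, `temperature`.
#' @export
fold_params <- function(temperature = 27) {
  key <- sprintf("T%.4f", temperature)
  if (exists(key, envir = .fold_env, inherits = FALSE))
    return(get(key, envir = .fold_env))
  TK <- temperature + 273.15
  rescale_stack <- function(dG37, dH) dH - TK * (dH - dG37) / .T37
  rescale_loop <- function(dG37) dG37 * TK / .T37

  st_tab <- read.csv(system.file("extdata", "nn_stacks.csv",
                                 package = "anomito"),
                     stringsAsFactors = FALSE)
  stack <- matrix(NA_real_, 6, 6, dimnames = list(.PAIR_TYPES, .PAIR_TYPES))
  for (r in seq_len(nrow(st_tab)))
    stack[st_tab$pair1[r], st_tab$pair2[r]] <-
      rescale_stack(st_tab$dG37[r], st_tab$dH[r])
  wob <- function(p) p %in% c("GU", "UG")
  for (p1 in .PAIR_TYPES) for (p2 in .PAIR_TYPES) {
    nw <- wob(p1) + wob(p2)
    if (nw == 1) stack[p1, p2] <- rescale_stack(-1.3, -8.0)
    if (nw == 2) stack[p1, p2] <- rescale_stack(-0.5, -5.0)
  }

  lp <- read.csv(system.file("extdata", "nn_loops.csv", package = "anomito"),
                 stringsAsFactors = FALSE)
  take <- function(type) {
    sub <- lp[lp$type == type, ]
    setNames(sub$dG37, sub$size)
  }
  extend <- function(tab, upto = 30) {
    sizes <- as.integer(names(tab))
    mx <- max(sizes)
    out <- rep(NA_real_, upto)
    out[sizes] <- tab
    coef <- 1.75 * .GAS_R * .T37
    for (n in seq_len(upto))
      if (is.na(out[n]))
        out[n] <- if (n > mx) tab[[as.character(mx)]] + coef * log(n / mx)
                  else Inf
    out
  }
  hairpin <- rescale_loop(extend(take("hairpin")))
  bulge <- rescale_loop(extend(take("bulge")))
  internal <- rescale_loop(extend(take("internal")))
  internal[1] <- Inf  # internal loops have >= 2 unpaired nt
  pars <- list(stack = stack, hairpin = hairpin, bulge = bulge,
               internal = internal, hp_ext = 1.75 * .GAS_R * TK,
               Ma = rescale_loop(lp$dG37[lp$type == "multibranch_a"]),
               Mb = rescale_loop(lp$dG37[lp$type == "multibranch_b"]),
               Mc = rescale_loop(lp$dG37[lp$type == "multibranch_c"]),
               maxloop = 30L, temperature = temperature)
  .fold_env[[key]] <- pars
  pars
}

.encode_rna <- function(seq) {
  seq <- chartr("Tt", "Uu", toupper(seq))
  codes <- c(A = 0L, C = 1L, G = 2L, U = 3L)
  v <- codes[strsplit(seq, "")[[1]]]
  v[is.na(v)] <- -1L  # N and friends never pair
  unname(v)
}

.pairing_to_db <- function(pairing) {
  db <- rep(".", length(pairing))
  db[pairing > seq_along(pairing)] <- "("
  db[pairing < seq_along(pairing) & pairing > 0] <- ")"
  paste(db, collapse = "")
}

.pair_list <- function(pairing) {
  i <- which(pairing > seq_along(pairing))
  cbind(i = i, j = pairing[i])
}

## prepare params list for the C++ core (finite sentinel for Inf)
.cpp_params <- function(pars, allow_wobble = TRUE) {
  clamp <- function(x) ifelse(is.finite(x), x, 1e9)
  list(stack = clamp(pars$stack), hairpin = clamp(pars$hairpin),
       hp_ext = pars$hp_ext, bulge = clamp(pars$bulge),
       internal = clamp(pars$internal), Ma = pars$Ma, Mb = pars$Mb,
       Mc = pars$Mc, maxloop = pars$maxloop, wobble = allow_wobble)
}

#' Minimum-free-energy folding with suboptimal structures
#'
#' Folds a nucleic-acid sequence (DNA input is read as RNA, T as U) by
#' nearest-neighbour dynamic programming and reports the MFE structure plus
#' up to `max_suboptimals` distinct suboptimal structures within
#' `energy_band` kcal/mol of the MFE (obtained by refolding with one MFE
#' base pair forbidden per round). The open chain (dG = 0) is returned when
#' no negative-energy structure exists.
#'
#' @param seq nucleic-acid string, 10 to 5000 nt; more than 20% N is
#'   rejected.
#' @param temperature folding temperature in degrees Celsius (default 27).
#' @param max_suboptimals maximum number of suboptimal structures
#'   (default 20; 0 skips the suboptimal search).
#' @param energy_band width of the suboptimal energy band in kcal/mol.
#' @param allow_wobble allow GU/UG wobble pairs (default `TRUE`). Note that
#'   strand symmetry (identical dG after reverse complementation) holds
#'   only for the Watson-Crick subset, i.e. with wobble disabled.
#' @return list of class `FoldResult`: `delta_g` (kcal/mol, <= 0),
#'   `structure` (dot-bracket string), `pairing` (1-based partner vector, 0
#'   = unpaired), `suboptimals` (data.frame `structure`, `delta_g`),
#'   `temperature`.
#' @export
fold_mfe <- function(seq, temperature = 27, max_suboptimals = 20L,
                     energy_band = 1.0, allow_wobble = TRUE) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 10 || n > 5000)
    stop("sequence length must be in [10, 5000]", call. = FALSE)
  nN <- nchar(gsub("[ACGTU]", "", chartr("T", "U", seq)))
  if (nN / n > 0.2)
    stop("ambiguity error: more than 20% of bases are not A/C/G/T/U",
         call. = FALSE)
  pars <- fold_params(temperature)
  enc <- .encode_rna(seq)
  cp <- .cpp_params(pars, allow_wobble)
  res <- .fold_dp(enc, cp, matrix(integer(0), 0, 2))
  pairing <- res$pairing + 1L  # 0 = unpaired
  pairing[pairing < 1L] <- 0L
  mfe <- res$energy

  subs <- data.frame(structure = character(0), delta_g = numeric(0),
                     stringsAsFactors = FALSE)
  if (max_suboptimals > 0 && mfe < 0) {
    pl <- .pair_list(pairing)
    ## candidate pairs to forbid: the outermost (closing) pair of each
    ## helix gives distinct refolds; refold attempts are capped so the
    ## search stays linear in the number of requested structures
    closing <- which(pl[, 1] == 1L |
                       pairing[pmax(pl[, 1] - 1L, 1L)] != pl[, 2] + 1L)
    ord <- c(closing, setdiff(seq_len(nrow(pl)), closing))
    max_attempts <- max(2L * max_suboptimals, 10L)
    seen <- .pairing_to_db(pairing)
    cand <- list()
    for (r in utils::head(ord, max_attempts)) {
      forbid <- matrix(c(pl[r, 1] - 1L, pl[r, 2] - 1L), 1, 2)
      alt <- .fold_dp(enc, cp, forbid)
      db <- .pairing_to_db(alt$pairing + 1L)
      if (db %in% seen) next
      if (alt$energy > mfe + energy_band + 1e-9) next
      seen <- c(seen, db)
      cand[[length(cand) + 1L]] <- data.frame(structure = db,
                                              delta_g = alt$energy,
                                              stringsAsFactors = FALSE)
      if (length(cand) >= max_suboptimals) break
    }
    if (length(cand)) {
      subs <- do.call(rbind, cand)
      subs <- subs[order(subs$delta_g), , drop = FALSE]
      rownames(subs) <- NULL
    }
  }
  structure(list(delta_g = mfe, structure = .pairing_to_db(pairing),
                 pairing = pairing, suboptimals = subs,
                 temperature = temperature),
            class = "FoldResult")
}

#' @export
print.FoldResult <- function(x, ...) {
  cat(sprintf("FoldResult: dG = %.2f kcal/mol at %g degC (%d suboptimals)\n",
              x$delta_g, x$temperature, nrow(x$suboptimals)))
  if (nchar(x$structure) <= 80) cat(" ", x$structure, "\n")
  invisible(x)
}

#' Free energy of a given structure (loop decomposition)
#'
#' Standalone evaluator of the packaged energy model for an explicit list
#' of base pairs; used by the enumeration reference and exported for
#' structure auditing. Returns `Inf` for structures containing a disallowed
#' loop (internal/bulge loops above the size cap, hairpin loops under 3 nt,
#' or non-pairable bases).
#'
#' @param seq nucleic-acid string.
#' @param pairs two-column matrix of 1-based pair indices (i < j), or an
#'   empty matrix for the open chain.
#' @param temperature degrees Celsius.
#' @param allow_wobble allow GU/UG pairs (default `TRUE`).
#' @return free energy in kcal/mol.
#' @export
structure_energy <- function(seq, pairs, temperature = 27,
                             allow_wobble = TRUE) {
  pars <- fold_params(temperature)
  enc <- .encode_rna(seq)
  n <- length(enc)
  if (is.null(pairs) || nrow(pairs) == 0) return(0)
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  ptype <- function(i, j) {
    a <- enc[i]; b <- enc[j]
    if (a < 0 || b < 0) return(NA_integer_)
    m <- matrix(NA_integer_, 4, 4)
    m[1, 4] <- 1L; m[4, 1] <- 2L; m[3, 2] <- 3L; m[2, 3] <- 4L
    if (allow_wobble) { m[3, 4] <- 5L; m[4, 3] <- 6L }
    m[a + 1, b + 1]
  }
  partner <- rep(0L, n)
  partner[pairs[, 1]] <- pairs[, 2]
  partner[pairs[, 2]] <- pairs[, 1]
  total <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    pt <- ptype(i, j)
    if (is.na(pt)) return(Inf)
    ## walk the loop closed by (i, j): children pairs + unpaired count
    children <- list(); unpaired <- 0L
    k <- i + 1L
    while (k < j) {
      if (partner[k] > k) {
        children[[length(children) + 1L]] <- c(k, partner[k])
        k <- partner[k] + 1L
      } else if (partner[k] != 0L) {
        return(Inf)  # crossing pair
      } else {
        unpaired <- unpaired + 1L
        k <- k + 1L
      }
    }
    nb <- length(children)
    if (nb == 0L) {                       # hairpin
      if (unpaired < 3) return(Inf)
      e <- if (unpaired <= 30) pars$hairpin[unpaired]
           else pars$hairpin[30] + pars$hp_ext * log(unpaired / 30)
    } else if (nb == 1L) {                # stack / bulge / internal
      k <- children[[1]][1]; l <- children[[1]][2]
      pt2 <- ptype(k, l)
      if (is.na(pt2)) return(Inf)
      n1 <- k - i - 1L; n2 <- j - l - 1L
      if (n1 + n2 == 0) e <- pars$stack[pt, pt2]
      else if (n1 + n2 > pars$maxloop) return(Inf)
      else if (n1 == 0 || n2 == 0) e <- pars$bulge[n1 + n2]
      else e <- pars$internal[n1 + n2]
    } else {                              # multibranch
      e <- pars$Ma + pars$Mb * (nb + 1) + pars$Mc * unpaired
    }
    if (!is.finite(e)) return(Inf)
    total <- total + e
  }
  total
}

#' Exhaustive-enumeration folding reference
#'
#' Enumerates every valid non-crossing structure (allowed pairs, minimum
#' hairpin loop 3) of a short sequence, evaluates each with
#' [structure_energy()], and returns the minimum. Independent of the
#' dynamic-programming fold; exponential in length, intended for sequences
#' up to ~30 nt.
#'
#' @param seq nucleic-acid string (<= 34 nt enforced).
#' @param temperature degrees Celsius.
#' @param allow_wobble allow GU/UG pairs (default `TRUE`).
#' @return list with `delta_g` (minimum over all structures and the open
#'   chain) and `n_structures` (number of non-empty structures enumerated).
#' @export
fold_enumerate <- function(seq, temperature = 27, allow_wobble = TRUE) {
  pars <- fold_params(temperature)
  enc <- .encode_rna(seq)
  n <- length(enc)
  if (n > 34) stop("enumeration reference limited to 34 nt", call. = FALSE)
  can_pair <- function(i, j) {
    a <- enc[i]; b <- enc[j]
    if (a < 0 || b < 0) return(FALSE)
    (a == 0 && b == 3) || (a == 3 && b == 0) || (a == 2 && b == 1) ||
      (a == 1 && b == 2) ||
      (allow_wobble && ((a == 2 && b == 3) || (a == 3 && b == 2)))
  }
  ptype <- function(i, j) {
    key <- paste0(c("A", "C", "G", "U")[enc[i] + 1],
                  c("A", "C", "G", "U")[enc[j] + 1])
    match(key, .PAIR_TYPES)
  }
  loopE <- function(i, j, pairs) {
    nb <- nrow(pairs)
    if (nb == 0L) {
      u <- j - i - 1L
      if (u < 3) return(Inf)
      if (u <= 30) return(pars$hairpin[u])
      return(pars$hairpin[30] + pars$hp_ext * log(u / 30))
    }
    if (nb == 1L) {
      n1 <- pairs[1, 1] - i - 1L; n2 <- j - pairs[1, 2] - 1L
      if (n1 + n2 == 0) return(pars$stack[ptype(i, j), ptype(pairs[1, 1],
                                                             pairs[1, 2])])
      if (n1 + n2 > pars$maxloop) return(Inf)
      if (n1 == 0 || n2 == 0) return(pars$bulge[n1 + n2])
      return(pars$internal[n1 + n2])
    }
    unp <- (j - i - 1L) - sum(pairs[, 2] - pairs[, 1] + 1L)
    pars$Ma + pars$Mb * (nb + 1) + pars$Mc * unp
  }
  ## every structure is evaluated; structures sharing the same top-level
  ## pair skeleton on an interval are carried as one energy vector.
  memoC <- new.env(parent = emptyenv())  # (i,j) paired -> energy vector
  memoL <- new.env(parent = emptyenv())  # open interval -> skeleton groups
  Cfun <- function(i, j) {
    key <- paste(i, j)
    if (exists(key, envir = memoC, inherits = FALSE))
      return(get(key, envir = memoC))
    out <- numeric(0)
    for (grp in Lfun(i + 1L, j - 1L)) {
      le <- loopE(i, j, grp$pairs)
      if (is.finite(le)) out <- c(out, le + grp$evec)
    }
    assign(key, out, envir = memoC)
    out
  }
  Lfun <- function(i, j) {
    if (j - i < 4) return(list(list(pairs = matrix(integer(0), 0, 2),
                                    evec = 0)))
    key <- paste(i, j)
    if (exists(key, envir = memoL, inherits = FALSE))
      return(get(key, envir = memoL))
    out <- Lfun(i + 1L, j)                      # i unpaired
    for (k in if (i + 4L <= j) (i + 4L):j else integer(0)) {
      if (!can_pair(i, k)) next
      ce <- Cfun(i, k)
      if (length(ce) == 0) next
      for (rest in Lfun(k + 1L, j)) {
        ev <- as.vector(outer(ce, rest$evec, `+`))
        out[[length(out) + 1L]] <- list(pairs = rbind(c(i, k), rest$pairs),
                                        evec = ev)
      }
    }
    assign(key, out, envir = memoL)
    out
  }
  groups <- Lfun(1L, n)
  best <- 0; nst <- 0L
  for (grp in groups) {
    if (nrow(grp$pairs) == 0) next   # open chain (dG = 0 baseline)
    nst <- nst + length(grp$evec)
    m <- min(grp$evec)
    if (m < best) best <- m
  }
  list(delta_g = best, n_structures = nst)
}

#' Write fold results in dot-bracket (Vienna) format
#'
#' @param folds named list of `FoldResult` objects (names used as record
#'   ids) or a single result.
#' @param seqs character vector of the folded sequences, same order.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(folds, seqs, path) {
  if (inherits(folds, "FoldResult")) folds <- list(fold = folds)
  con <- file(path, "w"); on.exit(close(con))
  ids <- names(folds)
  for (k in seq_along(folds)) {
    writeLines(sprintf("># %s dG = %.2f kcal/mol (T = %g degC)",
                       ids[k], folds[[k]]$delta_g, folds[[k]]$temperature),
               con)
    writeLines(chartr("T", "U", toupper(seqs[k])), con)
    writeLines(folds[[k]]$structure, con)
  }
  invisible(path)
}

## ---- tRNA structure --------------------------------------------------------

#' Classify a tRNA fold as cloverleaf or atypical
#'
#' Folds the sequence at tRNA scale and calls the structure a cloverleaf
#' iff the MFE structure has an acceptor stem of at least `min_acceptor`
#' consecutive base pairs starting from the outermost pair and exactly
#' three hairpin loops (D, anticodon and T arms).
#'
#' @param seq tRNA sequence, 40-120 nt.
#' @param temperature degrees Celsius.
#' @param min_acceptor minimum acceptor stem length in bp (default 4).
#' @return `"cloverleaf"` or `"atypical"`, with attribute `detail`.
#' @export
classify_trna_structure <- function(seq, temperature = 27, min_acceptor = 4L) {
  n <- nchar(seq)
  if (n < 40 || n > 120)
    stop("tRNA-scale classification expects 40-120 nt", call. = FALSE)
  f <- fold_mfe(seq, temperature = temperature, max_suboptimals = 0L)
  pairing <- f$pairing
  pl <- .pair_list(pairing)
  detail <- list(n_hairpins = 0L, acceptor = 0L)
  verdict <- "atypical"
  if (nrow(pl) > 0) {
    ## hairpin loops: pairs enclosing no other pair
    is_hairpin <- vapply(seq_len(nrow(pl)), function(r) {
      i <- pl[r, 1]; j <- pl[r, 2]
      span <- if (j - i > 1) (i + 1):(j - 1) else integer(0)
      all(pairing[span] == 0)
    }, logical(1))
    n_hp <- sum(is_hairpin)
    ## acceptor stem: consecutive stacked pairs from the outermost pair
    out <- which(pairing > 0)[1]
    acc <- 0L
    if (length(out) == 1 && !is.na(out)) {
      i <- out; j <- pairing[out]
      while (i < j && pairing[i] == j) {
        acc <- acc + 1L
        i <- i + 1L; j <- j - 1L
      }
    }
    detail <- list(n_hairpins = n_hp, acceptor = acc)
    if (n_hp == 3L && acc >= min_acceptor) verdict <- "cloverleaf"
  }
  attr(verdict, "detail") <- detail
  verdict
}

#' Construct a synthetic cloverleaf tRNA sequence
#'
#' Concatenates designed GC-rich stems (acceptor, D, anticodon, T) with
#' short loops; used to exercise the tRNA structure classifier with a known
#' ground truth.
#'
#' @param drop_d_arm omit the D arm (yielding an atypical two-armed fold).
#' @return DNA string.
#' @export
synthetic_trna <- function(drop_d_arm = FALSE) {
  acc <- "GGCGGCG"                       # acceptor stem, 7 bp
  d_stem <- "GCCG"; d_loop <- "TTAAATTA"  # D arm
  ac_stem <- "GGCGC"; ac_loop <- "TTCATAA" # anticodon arm
  t_stem <- "CGGCG"; t_loop <- "TTCAAAT"   # T arm
  d_arm <- if (drop_d_arm) "" else
    paste0(d_stem, d_loop, revcomp(d_stem))
  paste0(acc, "TA", d_arm, "A",
         ac_stem, ac_loop, revcomp(ac_stem), "A",
         t_stem, t_loop, revcomp(t_stem),
         "TA", revcomp(acc), "A")
}
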