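## depth_assoc: habitat-depth categories and the family-wise association
## between control-region folding free energy and depth, contrasting
## carcinized and non-carcinized lineages.
##
## Sign convention: "dG decreases with depth" means rho(depth, dG) < 0,
## i.e. the control region folds more stably (more negative dG) in deeper
## species. Per-species summaries are range midpoints, since the source
## data report ranges only.

#' Families treated as carcinized (crab-like body plan)
#'
#' Lithodidae and Porcellanidae are carcinized on the authority of the
#' comparative literature; Lomisidae is included as a further
#' convergently carcinized lineage. Editable by passing your own vector
#' wherever a `carcinized` argument is accepted.
#'
#' @return character vector of family names.
#' @export
carcinized_families <- function() c("Lithodidae", "Porcellanidae", "Lomisidae")

#' Load the packaged comparative habitat table
#'
#' Control-region length, AT content, repeat summaries, folding free-energy
#' ranges (kcal/mol), habitat depth ranges (m) and climate for anomuran and
#' outgroup species, transcribed from the comparative literature. Rows with
#' a `"Too compact"` control region have no numeric dG.
#'
#' @param path optional alternative CSV with the same columns.
#' @return data.frame with one row per species; adds derived columns
#'   `depth_mid`, `dg_mid` and `carcinized`.
#' @export
habitat_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "habitat_table.csv", package = "anomito")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tab$depth_mid <- (tab$depth_min + tab$depth_max) / 2
  tab$dg_mid <- (tab$dg_low + tab$dg_high) / 2
  tab$carcinized <- tab$family %in% carcinized_families()
  tab
}

#' Assign the habitat-depth category
#'
#' Half-open bins by depth midpoint: Intertidal `[0, 30)`, Shallow
#' `[30, 200)`, Upper bathyal `[200, 1000)`, Deep sea `[1000, Inf)`. A
#' terrestrial flag overrides the bins.
#'
#' @param depth_min,depth_max depth range in metres (>= 0).
#' @param terrestrial logical override.
#' @return category label (character).
#' @export
assign_depth_category <- function(depth_min, depth_max, terrestrial = FALSE) {
  if (terrestrial) return("Terrestrial")
  if (any(c(depth_min, depth_max) < 0)) stop("depths must be >= 0",
                                             call. = FALSE)
  mid <- (depth_min + depth_max) / 2
  if (mid < 30) "Intertidal"
  else if (mid < 200) "Shallow"
  else if (mid < 1000) "Upper bathyal"
  else "Deep sea"
}

#' Family-wise trend between control-region dG and habitat depth
#'
#' Spearman rank correlation between the depth midpoint and the dG
#' midpoint within each family, with a permutation p-value (depth labels
#' shuffled, fixed seed). Species without a numeric dG (e.g. "Too compact"
#' control regions) are excluded; families with fewer than `min_n` usable
#' records are skipped with a notice. Hydrothermal-vent taxa are excluded
#' by default and reported separately (their dG reflects vent conditions,
#' not depth alone).
#'
#' @param records habitat data.frame as from [habitat_table()].
#' @param min_n minimum usable records per family (default 4).
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed for the permutation test.
#' @param exclude_vent drop rows with `vent == TRUE` (default TRUE).
#' @return data.frame of class `TrendResult` with columns `family`, `n`,
#'   `spearman_rho`, `direction` (`decreasing`/`increasing`/`none` by sign
#'   of rho at |rho| > 0.3), `p_perm`, `vent_excluded`.
#' @export
dg_depth_trend <- function(records, min_n = 4L, n_perm = 10000L, seed = 1L,
                           exclude_vent = TRUE) {
  usable <- records[!is.na(records$dg_mid) & !is.na(records$depth_mid), ,
                    drop = FALSE]
  ## fully terrestrial rows carry no depth information
  if (!is.null(usable$terrestrial))
    usable <- usable[!(usable$terrestrial & usable$depth_max == 0), ,
                     drop = FALSE]
  n_vent <- 0L
  if (exclude_vent && !is.null(usable$vent)) {
    n_vent <- sum(usable$vent)
    usable <- usable[!usable$vent, , drop = FALSE]
  }
  fams <- unique(usable$family)
  rows <- list()
  for (fam in fams) {
    sub <- usable[usable$family == fam, ]
    if (nrow(sub) < min_n) {
      message("family ", fam, " skipped: only ", nrow(sub),
              " usable record(s)")
      next
    }
    if (stats::sd(sub$depth_mid) == 0 || stats::sd(sub$dg_mid) == 0) {
      message("family ", fam, " skipped: no depth or dG variation")
      next
    }
    rho <- cor(sub$depth_mid, sub$dg_mid, method = "spearman")
    ## permutation p: two-sided on |rho|
    set.seed(seed)
    perm <- replicate(n_perm,
                      cor(sample(sub$depth_mid), sub$dg_mid,
                          method = "spearman"))
    p <- (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
    dir <- if (is.na(rho) || abs(rho) <= 0.3) "none"
           else if (rho < 0) "decreasing" else "increasing"
    rows[[length(rows) + 1L]] <- data.frame(
      family = fam, n = nrow(sub), spearman_rho = rho, direction = dir,
      p_perm = p, vent_excluded = n_vent, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family = character(0), n = integer(0),
               spearman_rho = numeric(0), direction = character(0),
               p_perm = numeric(0), vent_excluded = integer(0),
               stringsAsFactors = FALSE)
  class(out) <- c("TrendResult", "data.frame")
  out
}

#' Contrast dG-depth trends between carcinized and non-carcinized families
#'
#' Summarizes trend directions per group and reports a sign-concordance
#' fraction (share of families matching their group's modal direction).
#' With a single family no contrast statistic is computed.
#'
#' @param trends result of [dg_depth_trend()].
#' @param carcinized character vector of carcinized family names.
#' @return list with `by_family` (family, group, direction), `summary`
#'   (per-group modal direction and concordance), and `contrast`
#'   (`TRUE` when the two groups' modal directions differ; `NA` when a
#'   group is empty or only one family is present).
#' @export
carcinization_contrast <- function(trends,
                                   carcinized = carcinized_families()) {
  if (nrow(trends) == 0) stop("no trends supplied", call. = FALSE)
  by_fam <- data.frame(
    family = trends$family,
    group = ifelse(trends$family %in% carcinized, "carcinized",
                   "non-carcinized"),
    direction = trends$direction,
    spearman_rho = trends$spearman_rho,
    stringsAsFactors = FALSE)
  modal <- function(x) names(sort(table(x), decreasing = TRUE))[1]
  summ <- do.call(rbind, lapply(split(by_fam, by_fam$group), function(g) {
    md <- modal(g$direction)
    data.frame(group = g$group[1], n_families = nrow(g),
               modal_direction = md,
               concordance = mean(g$direction == md),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  contrast <- if (nrow(summ) == 2 && nrow(by_fam) > 1)
    summ$modal_direction[1] != summ$modal_direction[2] else NA
  list(by_family = by_fam, summary = summ, contrast = contrast)
}
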