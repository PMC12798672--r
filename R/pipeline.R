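## cli_pipeline: orchestration of the analysis stages with a validated
## config, deterministic output layout and a machine-readable manifest.
## The exported functions are the entry points; each stage writes the TSV
## formats defined by its module.

.CONFIG_DEFAULTS <- list(
  input_genbank = NULL,      # dir or character vector of .gb files
  pairs_manifest = NULL,     # CSV: accession1, accession2, family, depth1, depth2
  habitat_csv = NULL,        # default: packaged table
  reference = "canonical37", # or "paper"
  window = 52L, step = 12L,
  fold_temperature = 27,
  max_suboptimals = 20L,
  cr_min_length = 50L,
  stages = c("composition", "gene_order", "kaks", "control_region",
             "depth_assoc"),
  seed = 1L,
  out_dir = "anomito_out")

#' Validate and complete a pipeline configuration
#'
#' Unknown keys are rejected; defaults fill the rest.
#'
#' @param config named list, or path to a YAML file with those keys.
#' @return completed config list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    stop("validation error: unknown config key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  out <- .CONFIG_DEFAULTS
  out[names(config)] <- config
  if (!out$reference %in% c("canonical37", "paper"))
    stop("validation error: reference must be 'canonical37' or 'paper'",
         call. = FALSE)
  out
}

.stage_log <- function(con, stage, msg) {
  line <- sprintf("[%s] %-14s %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the analysis pipeline end-to-end
#'
#' Reads the configured GenBank records, runs the enabled stages and
#' writes a deterministic output tree: `composition/`, `gene_order/`,
#' `selection/`, `control_region/`, `depth_assoc/` plus `manifest.json`
#' (package version, resolved config, config hash, seed).
#'
#' @param config see [pipeline_config()].
#' @param genomes optional list of `MitoGenome` objects used instead of
#'   reading `input_genbank` (convenient with the synthetic generator).
#' @return invisibly, a list with the per-stage results.
#' @export
run_pipeline <- function(config = list(), genomes = NULL) {
  cfg <- pipeline_config(config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(out, "run.log"), "w")
  on.exit(close(logcon))

  ## ingest
  if (is.null(genomes)) {
    paths <- cfg$input_genbank
    if (is.null(paths)) stop("no input: supply input_genbank or genomes",
                             call. = FALSE)
    if (length(paths) == 1 && dir.exists(paths))
      paths <- list.files(paths, pattern = "\\.gb$", full.names = TRUE)
    .stage_log(logcon, "ingest", paste("reading", length(paths), "records"))
    genomes <- lapply(sort(paths), read_genbank)
  }
  names(genomes) <- vapply(genomes, `[[`, character(1), "accession")
  write_feature_table(genomes, file.path(out, "features.tsv"))
  results <- list(genomes = genomes)

  if ("composition" %in% cfg$stages) {
    d <- file.path(out, "composition"); dir.create(d, showWarnings = FALSE)
    .stage_log(logcon, "composition", "per-record skew report")
    comp <- do.call(rbind, lapply(genomes, skew_report))
    write.table(comp, file.path(d, "composition.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    usage <- codon_usage(unlist(lapply(genomes, function(g)
      lapply(intersect(.PCGS, g$features$name), function(p)
        extract_cds(g, p)))))
    write.table(usage, file.path(d, "codon_usage.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    results$composition <- comp
  }

  if ("gene_order" %in% cfg$stages) {
    d <- file.path(out, "gene_order"); dir.create(d, showWarnings = FALSE)
    .stage_log(logcon, "gene_order", "typing and reference diffs")
    orders <- lapply(genomes, gene_order_from_genome)
    types <- write_gene_order_tables(
      orders, order_path = file.path(d, "gene_orders.tsv"),
      type_path = file.path(d, "arrangement_types.tsv"))
    ref <- ground_pattern(cfg$reference)
    diffs <- lapply(orders, function(o) diff_vs_reference(o, ref))
    bp <- vapply(orders, function(o) breakpoint_distance(o, ref), integer(1))
    write.table(data.frame(accession = names(bp),
                           breakpoints_vs_reference = bp),
                file.path(d, "breakpoints.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    results$gene_order <- list(orders = orders, types = types, diffs = diffs)
  }

  if ("kaks" %in% cfg$stages && !is.null(cfg$pairs_manifest)) {
    d <- file.path(out, "selection"); dir.create(d, showWarnings = FALSE)
    man <- read.csv(cfg$pairs_manifest, stringsAsFactors = FALSE)
    .stage_log(logcon, "kaks", paste(nrow(man), "pair(s)"))
    pairs <- lapply(seq_len(nrow(man)), function(i) {
      list(g1 = genomes[[man$accession1[i]]],
           g2 = genomes[[man$accession2[i]]],
           depth1 = man$depth1[i], depth2 = man$depth2[i])
    })
    rep_ <- depth_pair_report(pairs)
    write.table(rep_, file.path(d, "kaks_per_gene.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ## sliding windows per pair for the longest gene as a summary scan
    results$kaks <- rep_
  }

  if ("control_region" %in% cfg$stages) {
    d <- file.path(out, "control_region"); dir.create(d, showWarnings = FALSE)
    .stage_log(logcon, "control_region", "repeats, motifs, folding")
    cr_rows <- list(); folds <- list(); seqs <- character(0)
    for (g in genomes) {
      reg <- locate_control_region(g, min_length = cfg$cr_min_length)
      if (reg$status != "ok") {
        cr_rows[[g$accession]] <- data.frame(
          accession = g$accession, status = reg$status, length = NA,
          flank5 = NA, flank3 = NA, stringsAsFactors = FALSE)
        next
      }
      cr_rows[[g$accession]] <- data.frame(
        accession = g$accession, status = "ok", length = reg$length,
        flank5 = reg$flank5, flank3 = reg$flank3, stringsAsFactors = FALSE)
      tr <- find_tandem_repeats(reg$sequence)
      if (nrow(tr)) tr <- cbind(accession = g$accession, tr)
      mo <- annotate_motifs(reg$sequence, repeats = tr)
      if (nrow(mo)) mo <- cbind(accession = g$accession, mo)
      f <- fold_mfe(reg$sequence, temperature = cfg$fold_temperature,
                    max_suboptimals = cfg$max_suboptimals)
      folds[[g$accession]] <- f
      seqs[g$accession] <- reg$sequence
      write.table(tr, file.path(d, paste0(g$accession, "_repeats.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(mo, file.path(d, paste0(g$accession, "_motifs.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(do.call(rbind, cr_rows), file.path(d, "control_regions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(folds))
      write_vienna(folds, seqs, file.path(d, "structures.vienna"))
    results$control_region <- list(regions = do.call(rbind, cr_rows),
                                   folds = folds)
  }

  if ("depth_assoc" %in% cfg$stages) {
    d <- file.path(out, "depth_assoc"); dir.create(d, showWarnings = FALSE)
    .stage_log(logcon, "depth_assoc", "family-wise dG ~ depth trends")
    hab <- habitat_table(cfg$habitat_csv)
    trends <- suppressMessages(dg_depth_trend(hab, seed = cfg$seed))
    write.table(trends, file.path(d, "trends.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ctr <- carcinization_contrast(trends)
    write.table(ctr$summary, file.path(d, "carcinization_contrast.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results$depth_assoc <- list(trends = trends, contrast = ctr)
  }

  cfg_path <- file.path(out, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  manifest <- list(
    package = "anomito",
    version = as.character(utils::packageVersion("anomito")),
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    n_genomes = length(genomes),
    stages = cfg$stages)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

#' Write the packaged fixture set
#'
#' Copies the habitat and depth-category tables, writes both reference
#' ground patterns, and generates a default synthetic genome set (GenBank
#' flat files plus truth JSON side-files) spanning three planted
#' arrangement classes.
#'
#' @param outdir output directory.
#' @param n_genomes number of synthetic genomes (default 6).
#' @param seed base seed.
#' @return character vector of written paths, invisibly.
#' @export
make_fixtures <- function(outdir, n_genomes = 6L, seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (f in c("habitat_table.csv", "depth_categories.csv")) {
    src <- system.file("extdata", f, package = "anomito")
    file.copy(src, file.path(outdir, f), overwrite = TRUE)
    written <- c(written, file.path(outdir, f))
  }
  for (ref in c("canonical37", "paper")) {
    p <- file.path(outdir, paste0("ground_pattern_", ref, ".tsv"))
    write_gene_order_tables(list(ground_pattern(ref)), order_path = p)
    written <- c(written, p)
  }
  ## three planted arrangement classes
  plans <- list(
    list(),
    list(),
    list(),
    list(list(type = "transposition", gene = "trnI", after = "trnM")),
    list(list(type = "transposition", gene = "trnI", after = "trnM")),
    list(list(type = "inversion", genes = "trnW")))
  for (i in seq_len(n_genomes)) {
    sp <- genome_spec(
      rearrangements = plans[[((i - 1L) %% length(plans)) + 1L]],
      accession = sprintf("SYN%06d", i),
      taxon = sprintf("Synthetica exempli %d", i),
      seed = seed + i)
    g <- generate_genome(sp)
    gb <- file.path(outdir, paste0(sp$accession, ".gb"))
    write_genbank(g$genome, gb)
    tj <- file.path(outdir, paste0(sp$accession, "_truth.json"))
    jsonlite::write_json(g$truth, tj, auto_unbox = TRUE, digits = NA,
                         null = "null")
    written <- c(written, gb, tj)
  }
  invisible(written)
}
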