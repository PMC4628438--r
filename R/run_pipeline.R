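## End-to-end driver: config file in, six artifact files out.

.config_hash <- function(txt) {
  # tiny stable content hash for provenance headers (no crypto intent)
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.stage_seed <- function(global_seed, stage_index) {
  # deterministic per-stage seeds below 2^31 so stages rerun in isolation
  as.integer((as.double(global_seed) * 1009 + stage_index * 101) %% .Machine$integer.max)
}

#' Run the full AFLP diversity pipeline from a config
#'
#' Drives simulate (optional) -> score -> filter -> distance -> tree ->
#' haplotypes -> stats and writes all artifacts: scoring matrix TSV,
#' locus-quality TSV, PHYLIP distance matrix, Newick trees (supported
#' full-data + consensus), haplotype summary TSV and chi-square report
#' TSV. Every TSV embeds the global seed and a config hash in `#` header
#' lines; outputs are identical for identical config + seed.
#'
#' The config is a YAML file (or an equivalent named list) with keys:
#' \preformatted{
#' seed: 1
#' output_dir: out/
#' simulate:            # either this ...
#'   n_isolates: 93
#'   ...any simulation_config() argument...
#' input:               # ... or this
#'   intensities: path.csv
#'   metadata: path.csv
#'   control_isolates: [ID, ID.p2]
#' scoring: {t_high: 100, t_low: 50, max_conflict: 0.05}
#' bootstrap: {n_replicates: 1000, support_threshold: 95}
#' }
#'
#' @param config Path to a YAML config file, or a named list.
#' @return Invisibly, a list with the fitted `aflp_diversity` object and
#'   the paths of the written artifacts.
#' @export
run_aflp_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML path or a named list")
  seed <- as.integer(config$seed %||% 1L)
  outdir <- config$output_dir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  # hash the analysis-relevant config; where outputs land cannot change results
  chash <- .config_hash(paste(deparse(config[setdiff(names(config), "output_dir")]),
                              collapse = ""))
  hdr <- c(sprintf("aflpdiver %s", as.character(utils::packageVersion("aflpdiver"))),
           sprintf("seed=%d config_hash=%s", seed, chash))

  # -- inputs -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- .stage_seed(seed, 1L)
    sim <- simulate_aflp(do.call(simulation_config, sim_args))
    intensities <- sim$intensities
    metadata <- sim$truth$metadata
    control <- c(sim$truth$control_id, sim$truth$control_aliases)
    write_intensity_table(intensities, file.path(outdir, "intensities.csv"))
    write_isolate_metadata(metadata, file.path(outdir, "metadata.csv"))
  } else if (!is.null(config$input)) {
    path <- config$input$intensities
    if (is.null(path) || !file.exists(path)) {
      stop("pipeline stage 'input' failed: intensity file not found: ",
           if (is.null(path)) "(unset)" else path)
    }
    intensities <- read_intensity_table(path)
    metadata <- if (!is.null(config$input$metadata)) {
      read_isolate_metadata(config$input$metadata)
    } else NULL
    control <- config$input$control_isolates
  } else {
    stop("config must provide either 'simulate' or 'input'")
  }

  sc <- config$scoring %||% list()
  thresholds <- scoring_thresholds(t_high = sc$t_high %||% 100,
                                   t_low = sc$t_low %||% 50)
  bc <- config$bootstrap %||% list()
  bs <- bootstrap_config(n_replicates = bc$n_replicates %||% 1000L,
                         seed = .stage_seed(seed, 4L),
                         support_threshold = bc$support_threshold %||% 95)

  fit <- aflp_diversity(intensities, metadata = metadata,
                        thresholds = thresholds, control_isolates = control,
                        max_conflict = sc$max_conflict %||% 0.05,
                        bootstrap = bs)

  # -- artifacts ----------------------------------------------------------
  paths <- list(
    matrix = file.path(outdir, "matrix.tsv"),
    locus_quality = file.path(outdir, "locus_quality.tsv"),
    distances = file.path(outdir, "distances.phy"),
    tree = file.path(outdir, "tree.nwk"),
    consensus = file.path(outdir, "consensus.nwk"),
    haplotypes = file.path(outdir, "haplotypes.tsv"),
    chisq = file.path(outdir, "chisq.tsv")
  )
  write_binary_matrix(fit$matrix, paths$matrix, header_lines = hdr)
  if (!is.null(fit$locus_quality)) {
    con <- file(paths$locus_quality, "w")
    writeLines(paste0("# ", hdr), con)
    utils::write.table(fit$locus_quality, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  write_phylip_distance(fit$distances, paths$distances)
  write_newick(fit$tree, paths$tree)
  if (!is.null(fit$consensus)) write_newick(fit$consensus, paths$consensus)
  if (!is.null(fit$sharing)) {
    con <- file(paths$haplotypes, "w")
    writeLines(paste0("# ", hdr), con)
    utils::write.table(fit$sharing$per_haplotype, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  if (!is.null(fit$tests)) {
    rep_df <- do.call(rbind, lapply(names(fit$tests), function(nm) {
      t <- fit$tests[[nm]]
      data.frame(test = nm, statistic = round(t$statistic, 4), df = t$df,
                 p_value = signif(t$p_value, 4))
    }))
    con <- file(paths$chisq, "w")
    writeLines(paste0("# ", hdr), con)
    utils::write.table(rep_df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  invisible(list(fit = fit, paths = paths, seed = seed, config_hash = chash))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
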