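#' Intraspecific AFLP diversity analysis
#'
#' Runs the full dominant-marker diversity analysis on a fragment-
#' intensity table (or an already scored binary matrix): replicate-based
#' band calling, locus repeatability filtering, pairwise Dice distances,
#' UPGMA dendrogram with locus-bootstrap support and majority-rule
#' consensus, exact-match haplotype grouping, and — when metadata are
#' supplied — haplotype sharing across areas/crops plus Pearson
#' chi-square tests of the isolate frequency distributions (area x crop
#' homogeneity and one-way goodness-of-fit by area and by crop).
#'
#' Plate-control copies named in `control_isolates` are used for the
#' control-consistency locus filter and then dropped before distance,
#' tree and haplotype analyses, so the control enters those results once.
#'
#' @param x Either an intensity table `data.frame` (see
#'   [read_intensity_table()]) or a binary profile matrix (isolates x
#'   loci, entries 0/1). A matrix skips the scoring and filtering stages.
#' @param metadata Optional metadata data.frame covering every isolate.
#' @param thresholds A [scoring_thresholds()].
#' @param control_isolates Optional ids of plate copies of the control
#'   isolate; all but the first are removed after filtering.
#' @param max_conflict,require_polymorphic,require_control_consistent
#'   Passed to [filter_loci()].
#' @param bootstrap A [bootstrap_config()]; `NULL` skips bootstrapping
#'   (the tree is still built, without supports).
#' @return An object of class `"aflp_diversity"`: a list with components
#'   `matrix`, `locus_quality`, `n_loci_scored`, `distances`, `tree`,
#'   `consensus`, `clade_support`, `haplotypes`, `sharing`, `tests`,
#'   `params` and `call`.
#' @examples
#' sim <- simulate_aflp(simulation_config(n_isolates = 12, n_lineages = 3,
#'                                        n_loci = 20, mutation_rate = 0,
#'                                        dropout_prob = 0, seed = 42))
#' fit <- aflp_diversity(sim$intensities, metadata = sim$truth$metadata,
#'                       control_isolates = c(sim$truth$control_id,
#'                                            sim$truth$control_aliases),
#'                       bootstrap = bootstrap_config(n_replicates = 50, seed = 7))
#' print(fit)
#' @export
aflp_diversity <- function(x, metadata = NULL,
                           thresholds = scoring_thresholds(),
                           control_isolates = NULL,
                           max_conflict = 0.05,
                           require_polymorphic = TRUE,
                           require_control_consistent = !is.null(control_isolates),
                           bootstrap = bootstrap_config()) {
  cl <- match.call()
  if (is.matrix(x)) {
    validate_binary_matrix(x)
    m <- x
    quality <- NULL
    n_scored <- ncol(x)
  } else {
    scored <- score_matrix(x, thresholds = thresholds,
                           control_isolates = control_isolates)
    quality <- scored$quality
    n_scored <- ncol(scored$matrix)
    m <- filter_loci(scored$matrix, quality,
                     max_conflict = max_conflict,
                     require_polymorphic = require_polymorphic,
                     require_control_consistent = require_control_consistent)
  }
  if (!is.null(control_isolates) && length(control_isolates) > 1L) {
    drop <- intersect(control_isolates[-1L], rownames(m))
    m <- m[setdiff(rownames(m), drop), , drop = FALSE]
  }
  d <- dice_distance_matrix(m)
  if (!is.null(bootstrap)) {
    bs <- bootstrap_support(m, config = bootstrap)
    tree <- bs$tree; consensus <- bs$consensus; clade_support <- bs$clade_support
  } else {
    tree <- upgma(d); consensus <- NULL; clade_support <- NULL
  }
  haps <- assign_haplotypes(m)
  sharing <- NULL
  tests <- NULL
  if (!is.null(metadata)) {
    sharing <- sharing_summary(haps, metadata)
    md <- metadata[metadata$isolate_id %in% rownames(m), ]
    tests <- list()
    tab <- cross_tabulate(md)
    if (nrow(tab) >= 2L && ncol(tab) >= 2L &&
        !any(rowSums(tab) == 0) && !any(colSums(tab) == 0)) {
      tests$area_by_crop <- chi2_contingency(tab)
    }
    if (length(unique(md$area)) >= 2L) {
      tests$by_area <- chi2_goodness_of_fit(as.vector(table(md$area)))
    }
    if (length(unique(md$crop)) >= 2L) {
      tests$by_crop <- chi2_goodness_of_fit(as.vector(table(md$crop)))
    }
  }
  structure(list(matrix = m, locus_quality = quality, n_loci_scored = n_scored,
                 distances = d, tree = tree, consensus = consensus,
                 clade_support = clade_support, haplotypes = haps,
                 sharing = sharing, tests = tests,
                 params = list(thresholds = thresholds,
                               max_conflict = max_conflict,
                               require_polymorphic = require_polymorphic,
                               require_control_consistent = require_control_consistent,
                               bootstrap = bootstrap,
                               control_isolates = control_isolates),
                 call = cl),
            class = "aflp_diversity")
}

#' @export
print.aflp_diversity <- function(x, ...) {
  cat("AFLP diversity analysis\n")
  cat("  isolates: ", nrow(x$matrix), "   loci retained: ", ncol(x$matrix),
      " of ", x$n_loci_scored, " scored\n", sep = "")
  cat("  haplotypes: ", length(x$haplotypes$sizes), " (",
      sum(x$haplotypes$sizes >= 2L), " shared)\n", sep = "")
  if (!is.null(x$params$bootstrap)) {
    thr <- x$params$bootstrap$support_threshold
    cat("  significant clusters (support >= ", thr, "%, ",
        x$params$bootstrap$n_replicates, " replicates): ",
        count_significant_clusters(x$tree, thr), "\n", sep = "")
  }
  if (!is.null(x$tests)) {
    for (nm in names(x$tests)) {
      t <- x$tests[[nm]]
      cat(sprintf("  %s: chi-square = %.4f; df = %d; P = %s\n", nm,
                  t$statistic, t$df, format.pval(t$p_value, digits = 4)))
    }
  }
  invisible(x)
}

#' @export
summary.aflp_diversity <- function(object, ...) {
  print(object)
  if (!is.null(object$locus_quality)) {
    q <- object$locus_quality
    cat("\nlocus quality (", nrow(q), " scored loci):\n", sep = "")
    cat("  mean conflict fraction: ", sprintf("%.4f", mean(q$conflict_fraction)),
        "; polymorphic: ", sum(q$is_polymorphic), sep = "")
    if (!all(is.na(q$control_consistent))) {
      cat("; control-consistent: ", sum(q$control_consistent, na.rm = TRUE), sep = "")
    }
    cat("\n")
  }
  if (!is.null(object$sharing)) {
    cat("\n"); print(object$sharing)
  }
  invisible(object)
}

#' Plot the supported UPGMA dendrogram
#'
#' @param x An `aflp_diversity` object.
#' @param consensus Plot the majority-rule consensus instead of the
#'   full-data tree.
#' @param ... Passed to [ape::plot.phylo()].
#' @export
plot.aflp_diversity <- function(x, consensus = FALSE, ...) {
  tree <- if (consensus) x$consensus else x$tree
  if (is.null(tree)) stop("no tree of the requested kind in this object")
  ph <- tree_to_phylo(tree)
  ape::plot.phylo(ph, ...)
  if (!is.null(ph$node.label)) ape::nodelabels(ph$node.label, frame = "none", adj = c(1.1, -0.3), cex = 0.7)
  invisible(x)
}
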