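#' UPGMA dendrogram from a distance matrix
#'
#' Agglomerative clustering with size-weighted average linkage: the pair
#' of clusters at minimal average distance is merged, the new node is
#' placed at half the merge distance (so the tree is ultrametric), and
#' distances to the merged cluster are the size-weighted means of the
#' members' distances. Ties are broken deterministically: each cluster is
#' labelled by its lexicographically smallest member, and among tied
#' pairs the lexicographically smallest (label, label) pair merges first.
#' Children of a merge node are ordered smaller label first, so the
#' topology and its Newick form are reproducible regardless of input
#' order.
#'
#' @param dm Validated distance matrix (see [validate_distance_matrix()]),
#'   at least 2 isolates.
#' @return An `aflp_tree` with node heights and no supports.
#' @export
upgma <- function(dm) {
  validate_distance_matrix(dm)
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 isolates")
  labels <- rownames(dm)
  d <- dm
  nodes <- lapply(labels, .leaf_node)
  sizes <- rep(1L, n)
  clab <- labels                         # lexicographic tie-break label
  active <- seq_len(n)
  while (length(active) > 1L) {
    sub <- d[active, active, drop = FALSE]
    diag(sub) <- Inf
    dmin <- min(sub)
    hit <- which(sub <= dmin + 0, arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    # tie-break on sorted label pairs
    l1 <- pmin(clab[active[hit[, 1L]]], clab[active[hit[, 2L]]])
    l2 <- pmax(clab[active[hit[, 1L]]], clab[active[hit[, 2L]]])
    pick <- order(l1, l2)[1L]
    i <- active[hit[pick, 1L]]
    j <- active[hit[pick, 2L]]
    if (clab[i] > clab[j]) { tmp <- i; i <- j; j <- tmp }
    h <- dmin / 2
    kids <- list(nodes[[i]], nodes[[j]])
    nodes[[i]] <- .internal_node(kids, height = h)
    # size-weighted average linkage update into slot i
    rest <- setdiff(active, c(i, j))
    if (length(rest) > 0L) {
      upd <- (sizes[i] * d[i, rest] + sizes[j] * d[j, rest]) / (sizes[i] + sizes[j])
      d[i, rest] <- upd
      d[rest, i] <- upd
    }
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  .new_tree(nodes[[active]], sort(labels))
}

#' Bootstrap configuration
#'
#' @param n_replicates Number of locus resamples (default 1000).
#' @param seed Integer RNG seed.
#' @param support_threshold Support percentage above which a cluster is
#'   called significant (default 95; must exceed 50).
#' @return A list of class `"bootstrap_config"`.
#' @export
bootstrap_config <- function(n_replicates = 1000L, seed = 1L,
                             support_threshold = 95) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (support_threshold <= 50 || support_threshold > 100) {
    stop("support_threshold must lie in (50, 100]")
  }
  structure(list(n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 support_threshold = support_threshold),
            class = "bootstrap_config")
}

#' Locus-bootstrap support for a UPGMA dendrogram
#'
#' For each replicate, loci (characters) are resampled with replacement
#' to the original count, Dice distances and the UPGMA tree are
#' recomputed, and each clade of the full-data tree is scored by the
#' percentage of replicate trees containing exactly that leaf subset as a
#' cluster. Loci — not isolates — are resampled, the standard design for
#' dominant-marker fingerprints. Also returns the majority-rule (>50%)
#' consensus of the replicate trees.
#'
#' @param m Binary profile matrix, at least 3 isolates and 2 loci.
#' @param config A [bootstrap_config()].
#' @inheritParams dice_distance
#' @return A list with `tree` (the full-data UPGMA tree annotated with
#'   supports), `consensus` (heightless majority-rule consensus tree with
#'   supports), and `clade_support` (data.frame of clades with their
#'   replicate frequencies).
#' @export
bootstrap_support <- function(m, config = bootstrap_config(),
                              all_zero = c("zero", "error")) {
  all_zero <- match.arg(all_zero)
  validate_binary_matrix(m)
  if (nrow(m) < 3L) stop("need at least 3 isolates to bootstrap")
  if (ncol(m) < 2L) stop("need at least 2 loci to bootstrap")
  full <- upgma(dice_distance_matrix(m, all_zero = all_zero))
  counts <- new.env(hash = TRUE, parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  for (r in seq_len(config$n_replicates)) {
    idx <- sample.int(ncol(m), ncol(m), replace = TRUE)
    mr <- m[, idx, drop = FALSE]
    colnames(mr) <- sprintf("L%d", seq_along(idx))   # keep colnames unique
    tr <- upgma(dice_distance_matrix(mr, all_zero = all_zero))
    keys <- vapply(tree_clades(tr, include_root = TRUE)$clade, .clade_key, "")
    for (k in unique(keys)) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]], 0L)
  support_map <- as.list(100 * freq / config$n_replicates)
  names(support_map) <- keys
  full$root <- .annotate_supports(full$root, support_map)
  # clades of the full tree that never occurred in a replicate get 0
  full$root <- .zero_fill_supports(full$root)
  consensus <- .majority_consensus(keys, freq, config$n_replicates, tree_leaves(full))
  clade_support <- data.frame(
    size = vapply(strsplit(keys, "\r", fixed = TRUE), length, 0L),
    support = 100 * freq / config$n_replicates,
    row.names = NULL
  )
  clade_support$clade <- strsplit(keys, "\r", fixed = TRUE)
  clade_support <- clade_support[order(-clade_support$support, -clade_support$size), ]
  rownames(clade_support) <- NULL
  list(tree = full, consensus = consensus, clade_support = clade_support)
}

.zero_fill_supports <- function(node) {
  if (.is_leaf(node)) return(node)
  if (is.na(node$support)) node$support <- 0
  node$children <- lapply(node$children, .zero_fill_supports)
  node
}

## Build the majority-rule consensus tree from clade frequencies.
## Clades occurring in >50% of replicates are pairwise compatible, so the
## tree is assembled by nesting each clade under the smallest clade that
## strictly contains it.
.majority_consensus <- function(keys, freq, n_replicates, leaves) {
  sets <- strsplit(keys, "\r", fixed = TRUE)
  keep <- freq > n_replicates / 2
  sets <- sets[keep]
  sup <- 100 * freq[keep] / n_replicates
  # ensure the root clade is present
  if (!any(vapply(sets, function(s) identical(sort(s), sort(leaves)), TRUE))) {
    sets <- c(sets, list(sort(leaves)))
    sup <- c(sup, 100)
  }
  ord <- order(lengths(sets))              # small to large
  sets <- sets[ord]; sup <- sup[ord]
  build <- function(members, pool_idx, support) {
    # children clades: maximal kept clades strictly inside `members`
    inside <- pool_idx[vapply(pool_idx, function(i) {
      length(sets[[i]]) < length(members) && all(sets[[i]] %in% members)
    }, TRUE)]
    taken <- character(0)
    children <- list()
    for (i in rev(inside)) {               # largest first
      s <- sets[[i]]
      if (any(s %in% taken)) next
      children <- c(children, list(build(s, inside, sup[i])))
      taken <- c(taken, s)
    }
    for (lf in setdiff(members, taken)) children <- c(children, list(.leaf_node(lf)))
    # deterministic child order: by smallest leaf label
    first <- vapply(children, function(ch) .node_leaves(ch)[1L], "")
    children <- children[order(first)]
    .internal_node(children, height = NA_real_, support = support)
  }
  root <- build(sort(leaves), seq_along(sets), 100)
  .new_tree(root, sort(leaves))
}
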