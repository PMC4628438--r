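## Dendrogram representation: a rooted tree of nested lists.
## Leaf: list(label = <isolate id>). Internal: list(children = <list of
## nodes>, height = <merge distance / 2, NA if heightless>, support =
## <bootstrap %, NA if not annotated>). The wrapper class "aflp_tree"
## carries the root and the leaf set. Heights are ultrametric by
## construction in upgma(); consensus trees are heightless.

.leaf_node <- function(label) list(label = label)

.internal_node <- function(children, height = NA_real_, support = NA_real_) {
  list(children = children, height = height, support = support)
}

.is_leaf <- function(node) !is.null(node$label)

.new_tree <- function(root, leaves) {
  structure(list(root = root, leaves = leaves), class = "aflp_tree")
}

.node_leaves <- function(node) {
  if (.is_leaf(node)) return(node$label)
  sort(unlist(lapply(node$children, .node_leaves)))
}

#' Leaf labels of a dendrogram
#' @param tree An `aflp_tree`.
#' @return Character vector of leaf (isolate) labels.
#' @export
tree_leaves <- function(tree) {
  stopifnot(inherits(tree, "aflp_tree"))
  tree$leaves
}

.clade_key <- function(labels) paste(sort(labels), collapse = "\r")

## Walk internal nodes; fn(node, leaves, is_root, parent_height) called on each.
.walk_internal <- function(node, fn, is_root = TRUE, parent_height = NA_real_) {
  if (.is_leaf(node)) return(invisible(NULL))
  fn(node, .node_leaves(node), is_root, parent_height)
  for (ch in node$children) .walk_internal(ch, fn, FALSE, node$height)
  invisible(NULL)
}

#' Clades of a dendrogram
#'
#' Returns, for every internal node, the sorted set of leaf labels it
#' subtends, together with the node's height and bootstrap support.
#'
#' @param tree An `aflp_tree`.
#' @param include_root Keep the root (the trivial all-leaves clade)?
#' @return A data.frame with columns `clade` (list column of character
#'   vectors), `size`, `height`, `support`.
#' @export
tree_clades <- function(tree, include_root = TRUE) {
  stopifnot(inherits(tree, "aflp_tree"))
  acc <- new.env()
  acc$clade <- list(); acc$height <- numeric(); acc$support <- numeric(); acc$root <- logical()
  .walk_internal(tree$root, function(node, leaves, is_root, ph) {
    i <- length(acc$clade) + 1L
    acc$clade[[i]] <- leaves
    acc$height[i] <- node$height
    acc$support[i] <- node$support
    acc$root[i] <- is_root
  })
  out <- data.frame(size = lengths(acc$clade), height = acc$height,
                    support = acc$support, is_root = acc$root)
  out$clade <- acc$clade
  if (!include_root) out <- out[!out$is_root, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.annotate_supports <- function(node, support_map) {
  if (.is_leaf(node)) return(node)
  node$support <- support_map[[.clade_key(.node_leaves(node))]]
  if (is.null(node$support)) node$support <- NA_real_
  node$children <- lapply(node$children, .annotate_supports, support_map = support_map)
  node
}

.fmt_len <- function(x) {
  s <- sprintf("%.10f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", ".0", s)
}

.newick_node <- function(node, parent_height) {
  if (.is_leaf(node)) {
    if (is.na(parent_height)) return(node$label)
    return(paste0(node$label, ":", .fmt_len(parent_height)))
  }
  inner <- paste(vapply(node$children, .newick_node, "", parent_height = node$height),
                 collapse = ",")
  lab <- if (is.na(node$support)) "" else sprintf("%d", as.integer(round(node$support)))
  blen <- if (is.na(parent_height) || is.na(node$height)) "" else
    paste0(":", .fmt_len(parent_height - node$height))
  paste0("(", inner, ")", lab, blen)
}

#' Newick serialization of a dendrogram
#'
#' Branch lengths are derived from node heights (child branch length =
#' parent height minus child height; leaves sit at height 0). Bootstrap
#' supports, where present, become integer-rounded internal node labels —
#' the most widely parsed convention. Heightless trees (majority-rule
#' consensus) are written without branch lengths.
#'
#' @param tree An `aflp_tree`.
#' @return A single Newick string terminated by `;`.
#' @export
newick_string <- function(tree) {
  stopifnot(inherits(tree, "aflp_tree"))
  paste0(.newick_node(tree$root, NA_real_), ";")
}

#' Write a dendrogram to a Newick file
#'
#' @param tree An `aflp_tree` (supports in \[0, 100\] or absent).
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [newick_string()] for the serialization rules.
#' @export
write_newick <- function(tree, path) {
  sup <- tree_clades(tree)$support
  if (any(!is.na(sup) & (sup < 0 | sup > 100))) {
    stop("supports must lie in [0, 100]")
  }
  writeLines(newick_string(tree), path)
  invisible(path)
}

#' Convert a dendrogram to an ape "phylo" object
#'
#' Convenience bridge to the wider phylogenetics ecosystem (plotting,
#' comparison, re-export). Supports become `node.label`.
#'
#' @param tree An `aflp_tree`.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
tree_to_phylo <- function(tree) {
  ape::read.tree(text = newick_string(tree))
}

#' Count significant clusters in a supported dendrogram
#'
#' Counts internal nodes (root excluded) whose bootstrap support meets
#' `threshold`. Runs of equal-height merges are first collapsed into
#' polytomies, so a group of isolates with identical profiles — which
#' every bootstrap replicate reproduces trivially — contributes a single
#' clade rather than a chain of 100%-supported binary nodes.
#'
#' @param tree An `aflp_tree` with bootstrap supports (see
#'   [bootstrap_support()]).
#' @param threshold Support percentage a cluster must reach (default 95).
#' @return Integer count of significant clusters.
#' @export
count_significant_clusters <- function(tree, threshold = 95) {
  cl <- tree_clades(tree, include_root = TRUE)
  if (all(is.na(cl$support[!cl$is_root]))) {
    stop("tree carries no bootstrap supports; run bootstrap_support() first")
  }
  n <- 0L
  .walk_internal(tree$root, function(node, leaves, is_root, parent_height) {
    if (is_root) return(invisible(NULL))
    collapsed <- !is.na(parent_height) && !is.na(node$height) &&
      abs(parent_height - node$height) <= 1e-12
    if (collapsed) return(invisible(NULL))
    if (!is.na(node$support) && node$support >= threshold) n <<- n + 1L
  })
  n
}

#' @export
print.aflp_tree <- function(x, ...) {
  cl <- tree_clades(x, include_root = FALSE)
  sup <- cl$support[!is.na(cl$support)]
  cat("UPGMA dendrogram: ", length(x$leaves), " leaves, ",
      nrow(cl) + 1L, " internal nodes",
      if (is.na(x$root$height)) " (heightless consensus)" else
        sprintf(", root height %.4f", x$root$height),
      "\n", sep = "")
  if (length(sup) > 0L) {
    cat(sprintf("bootstrap supports on %d nodes: min %.0f / median %.0f / max %.0f\n",
                length(sup), min(sup), stats::median(sup), max(sup)))
  }
  invisible(x)
}
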