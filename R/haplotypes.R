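#' Group isolates into haplotypes by exact profile identity
#'
#' Two isolates share an AFLP haplotype when their binary profiles agree
#' at every retained locus — the natural notion of a clonal multilocus
#' genotype for dominant markers. An optional mismatch tolerance
#' (`max_mismatch > 0`, single-linkage closure over profiles within that
#' Hamming distance) is provided for sensitivity analysis only; the
#' default is exact matching.
#'
#' @param m Binary profile matrix (isolates x loci).
#' @param max_mismatch Maximum number of locus mismatches tolerated
#'   within a haplotype (default 0 = exact identity).
#' @return A list of class `"haplotype_assignment"` with
#'   `haplotype_of` (named integer vector, isolate -> haplotype index,
#'   indices ordered by first occurrence), `profiles` (haplotype x locus
#'   matrix; for `max_mismatch > 0` the first member's profile), and
#'   `sizes` (member counts).
#' @export
assign_haplotypes <- function(m, max_mismatch = 0L) {
  validate_binary_matrix(m)
  if (max_mismatch == 0L) {
    key <- apply(m, 1L, paste, collapse = "")
    idx <- match(key, unique(key))
  } else {
    # single-linkage closure over profiles within max_mismatch
    hd <- as.matrix(stats::dist(m, method = "manhattan"))
    adj <- hd <= max_mismatch
    n <- nrow(m)
    idx <- rep(NA_integer_, n)
    comp <- 0L
    for (i in seq_len(n)) {
      if (!is.na(idx[i])) next
      comp <- comp + 1L
      frontier <- i
      while (length(frontier) > 0L) {
        idx[frontier] <- comp
        frontier <- which(is.na(idx) & colSums(adj[frontier, , drop = FALSE]) > 0L)
      }
    }
  }
  sizes <- as.integer(table(factor(idx, levels = seq_len(max(idx)))))
  first <- match(seq_len(max(idx)), idx)
  profiles <- m[first, , drop = FALSE]
  rownames(profiles) <- sprintf("H%03d", seq_len(max(idx)))
  haplotype_of <- stats::setNames(idx, rownames(m))
  structure(list(haplotype_of = haplotype_of, profiles = profiles, sizes = sizes),
            class = "haplotype_assignment")
}

#' @export
print.haplotype_assignment <- function(x, ...) {
  cat(length(x$sizes), "haplotypes among", length(x$haplotype_of), "isolates;",
      sum(x$sizes >= 2L), "shared (size >= 2)\n")
  invisible(x)
}

#' Summarize haplotype sharing across metadata categories
#'
#' Reports how many haplotypes are shared (two or more members), the
#' size range of shared haplotypes, and for every haplotype its area and
#' crop composition — in particular whether members span multiple areas
#' or include external-origin isolates, the signature of widespread
#' clonal lineages.
#'
#' @param assignment A [assign_haplotypes()] result.
#' @param metadata Metadata data.frame covering every isolate
#'   (`isolate_id`, `area`, `crop`, `origin`).
#' @return A list of class `"sharing_summary"` with scalar counts
#'   (`n_haplotypes`, `n_shared`, `n_unique`, `shared_size_range`,
#'   `n_shared_multi_area`, `n_shared_with_external`) and `per_haplotype`,
#'   a data.frame with one row per haplotype.
#' @export
sharing_summary <- function(assignment, metadata) {
  stopifnot(inherits(assignment, "haplotype_assignment"))
  validate_isolate_metadata(metadata)
  isolates <- names(assignment$haplotype_of)
  missing <- setdiff(isolates, metadata$isolate_id)
  if (length(missing) > 0L) {
    stop("isolate(s) missing metadata: ", paste(missing, collapse = ", "))
  }
  md <- metadata[match(isolates, metadata$isolate_id), ]
  hap <- assignment$haplotype_of
  per <- do.call(rbind, lapply(seq_along(assignment$sizes), function(h) {
    sel <- hap == h
    data.frame(
      haplotype = rownames(assignment$profiles)[h],
      size = sum(sel),
      members = paste(isolates[sel], collapse = ","),
      areas = paste(sort(unique(md$area[sel])), collapse = ","),
      crops = paste(sort(unique(md$crop[sel])), collapse = ","),
      multi_area = length(unique(md$area[sel])) > 1L,
      has_external = any(md$origin[sel] == "external"),
      stringsAsFactors = FALSE
    )
  }))
  shared <- per$size >= 2L
  structure(list(
    n_haplotypes = nrow(per),
    n_shared = sum(shared),
    n_unique = sum(!shared),
    shared_size_range = if (any(shared)) range(per$size[shared]) else c(NA_integer_, NA_integer_),
    n_shared_multi_area = sum(shared & per$multi_area),
    n_shared_with_external = sum(shared & per$has_external),
    per_haplotype = per
  ), class = "sharing_summary")
}

#' @export
print.sharing_summary <- function(x, ...) {
  cat(x$n_haplotypes, "haplotypes:", x$n_shared, "shared,", x$n_unique, "unique\n")
  if (x$n_shared > 0L) {
    cat("shared haplotype sizes ", x$shared_size_range[1L], "-",
        x$shared_size_range[2L], "; ", x$n_shared_multi_area,
        " span multiple areas; ", x$n_shared_with_external,
        " include external isolates\n", sep = "")
  }
  invisible(x)
}
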