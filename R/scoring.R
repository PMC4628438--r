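#' Band-calling thresholds
#'
#' Two RFU thresholds govern presence calls from dual technical
#' replicates: `t_high` (default 100), the confident-signal level, and
#' `t_low` (default 50), the absolute minimum distinguishable from
#' background noise. Both are inclusive (a signal exactly at the
#' threshold counts), a deliberate resolution of the boundary the
#' verbal rule leaves open.
#'
#' @param t_high Confident-presence threshold in RFU.
#' @param t_low Minimum reliable signal in RFU.
#' @return A list of class `"scoring_thresholds"`.
#' @export
scoring_thresholds <- function(t_high = 100, t_low = 50) {
  if (!is.numeric(t_high) || !is.numeric(t_low) || t_low < 0 || t_low > t_high) {
    stop("thresholds must satisfy 0 <= t_low <= t_high")
  }
  structure(list(t_high = t_high, t_low = t_low), class = "scoring_thresholds")
}

#' Score one band from dual-replicate intensities
#'
#' A fragment is called present (1) when both replicates support it:
#' either both signals reach `t_high`, or the replicates disagree with
#' one at `t_high` and the other still at or above `t_low`. Equivalently
#' (and this is the implemented closed form):
#' `max(i1, i2) >= t_high` and `min(i1, i2) >= t_low`.
#' Otherwise the band is absent (0). The rule is symmetric in the two
#' replicates and monotone in each intensity.
#'
#' @param i1,i2 Signal intensities (RFU) of the two technical
#'   replicates; vectorized.
#' @param thresholds A [scoring_thresholds()].
#' @return Integer vector of 0/1 calls.
#' @export
score_band <- function(i1, i2, thresholds = scoring_thresholds()) {
  if (any(is.na(i1)) || any(is.na(i2)) || any(i1 < 0) || any(i2 < 0)) {
    stop("intensities must be non-negative")
  }
  as.integer(pmax(i1, i2) >= thresholds$t_high & pmin(i1, i2) >= thresholds$t_low)
}

#' Score a full intensity table into a binary profile matrix
#'
#' Applies [score_band()] to every isolate x locus cell and computes
#' per-locus quality diagnostics:
#' \describe{
#'   \item{conflict_fraction}{share of isolates with a *strong* replicate
#'     disagreement at the locus — one replicate at or above `t_high`,
#'     the other below `t_low`. Mid-zone disagreements are not counted
#'     because the calling rule itself resolves them.}
#'   \item{is_polymorphic}{both call values observed among isolates.}
#'   \item{control_consistent}{the designated plate-control isolate (its
#'     copies named in `control_isolates`) receives the same call on
#'     every plate; `NA` when no control is designated.}
#' }
#'
#' A locus absent from an isolate's records is taken as intensity 0 in
#' both replicates (fragment tables routinely omit absent peaks); a locus
#' present in exactly one replicate's records is an error.
#'
#' @param table Validated intensity table (see [read_intensity_table()]).
#' @param thresholds A [scoring_thresholds()].
#' @param control_isolates Optional character vector of isolate ids that
#'   are plate copies of the same biological control.
#' @return A list with `matrix` (binary isolate x locus matrix, first-
#'   appearance order) and `quality` (data.frame, one row per locus).
#' @export
score_matrix <- function(table, thresholds = scoring_thresholds(),
                         control_isolates = NULL) {
  validate_intensity_table(table)
  isolates <- unique(table$isolate_id)
  loci <- unique(table$locus_id)
  i1 <- matrix(0, length(isolates), length(loci), dimnames = list(isolates, loci))
  i2 <- i1
  seen1 <- matrix(FALSE, length(isolates), length(loci), dimnames = list(isolates, loci))
  seen2 <- seen1
  r1 <- table$replicate == 1L
  idx1 <- cbind(match(table$isolate_id[r1], isolates), match(table$locus_id[r1], loci))
  idx2 <- cbind(match(table$isolate_id[!r1], isolates), match(table$locus_id[!r1], loci))
  i1[idx1] <- table$intensity[r1]
  i2[idx2] <- table$intensity[!r1]
  seen1[idx1] <- TRUE
  seen2[idx2] <- TRUE
  odd <- which(xor(seen1, seen2), arr.ind = TRUE)
  if (nrow(odd) > 0L) {
    stop("isolate ", isolates[odd[1L, 1L]], " has a single replicate at locus ",
         loci[odd[1L, 2L]])
  }
  calls <- matrix(score_band(as.vector(i1), as.vector(i2), thresholds),
                  nrow = length(isolates), dimnames = list(isolates, loci))
  conflict <- pmax(i1, i2) >= thresholds$t_high & pmin(i1, i2) < thresholds$t_low
  quality <- data.frame(
    locus_id = loci,
    conflict_fraction = colMeans(conflict),
    is_polymorphic = apply(calls, 2L, function(x) length(unique(x)) > 1L),
    control_consistent = NA,
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(control_isolates)) {
    ctrl <- intersect(control_isolates, isolates)
    if (length(ctrl) == 0L) {
      stop("none of the designated control isolates appear in the table: ",
           paste(control_isolates, collapse = ", "))
    }
    quality$control_consistent <-
      apply(calls[ctrl, , drop = FALSE], 2L, function(x) length(unique(x)) == 1L)
  }
  list(matrix = calls, quality = quality)
}

#' Filter loci for repeatability, polymorphism and control consistency
#'
#' Reproducibility is the known weak point of restriction-fragment
#' markers; only loci that score consistently between technical
#' replicates (and, optionally, on the plate control) are retained for
#' distance and haplotype analyses.
#'
#' @param matrix Binary profile matrix from [score_matrix()].
#' @param quality Matching locus-quality data.frame.
#' @param max_conflict Maximum tolerated `conflict_fraction` (default
#'   0.05, i.e. strong replicate disagreement in at most 5% of isolates).
#' @param require_polymorphic Drop monomorphic loci (default `TRUE`) —
#'   they carry no information for Dice distances.
#' @param require_control_consistent Drop loci on which the plate control
#'   scores differently across plates (default `TRUE`; loci with no
#'   control information pass).
#' @return The matrix restricted to retained loci, original locus order
#'   preserved, isolate set unchanged.
#' @export
filter_loci <- function(matrix, quality, max_conflict = 0.05,
                        require_polymorphic = TRUE,
                        require_control_consistent = TRUE) {
  validate_binary_matrix(matrix)
  if (!setequal(quality$locus_id, colnames(matrix))) {
    stop("quality table must cover exactly the loci of the matrix")
  }
  q <- quality[match(colnames(matrix), quality$locus_id), ]
  keep <- q$conflict_fraction <= max_conflict
  if (require_polymorphic) keep <- keep & q$is_polymorphic
  if (require_control_consistent) keep <- keep & (is.na(q$control_consistent) | q$control_consistent)
  if (!any(keep)) {
    stop("locus filter removed every locus; relax max_conflict or the flags")
  }
  matrix[, keep, drop = FALSE]
}
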