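#' Dice distance between two binary profiles
#'
#' With `a` shared presences, `b` and `c` one-sided presences, the Dice
#' similarity is `2a / (2a + b + c)` and the distance is its complement.
#' Shared absences never contribute — appropriate for dominant markers,
#' where a missing band is uninformative about genotype identity. Two
#' all-zero profiles are identical observations and get distance 0 by
#' default; set `all_zero = "error"` to treat the undefined ratio
#' strictly.
#'
#' @param x,y Binary vectors of equal length.
#' @param all_zero `"zero"` (default) or `"error"`.
#' @return Distance in \[0, 1\].
#' @export
dice_distance <- function(x, y, all_zero = c("zero", "error")) {
  all_zero <- match.arg(all_zero)
  if (length(x) != length(y)) stop("profiles differ in length")
  if (length(x) < 1L) stop("profiles must have at least one locus")
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1))) stop("profiles must be binary")
  a <- sum(x == 1 & y == 1)
  b <- sum(x == 1 & y == 0)
  cc <- sum(x == 0 & y == 1)
  if (a + b + cc == 0L) {
    if (all_zero == "error") stop("Dice distance undefined for two all-zero profiles")
    return(0)
  }
  1 - 2 * a / (2 * a + b + cc)
}

#' Pairwise Dice distance matrix
#'
#' Computes all pairwise Dice distances between the rows of a binary
#' profile matrix (vectorized via cross-products).
#'
#' @param m Binary profile matrix (isolates x loci), at least 2 isolates
#'   and 1 locus.
#' @inheritParams dice_distance
#' @return Symmetric numeric matrix with zero diagonal, entries in
#'   \[0, 1\], isolate dimnames.
#' @export
dice_distance_matrix <- function(m, all_zero = c("zero", "error")) {
  all_zero <- match.arg(all_zero)
  validate_binary_matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 isolates for a distance matrix")
  storage.mode(m) <- "double"
  a <- tcrossprod(m)                       # shared presences
  r <- rowSums(m)
  denom <- outer(r, r, "+")
  if (all_zero == "error" && sum(r == 0) >= 2L) {
    stop("Dice distance undefined for two all-zero profiles")
  }
  s <- ifelse(denom == 0, 1, 2 * a / denom)
  d <- 1 - s
  diag(d) <- 0
  d <- (d + t(d)) / 2                      # enforce exact symmetry
  dimnames(d) <- list(rownames(m), rownames(m))
  validate_distance_matrix(d)
  d
}

#' Validate a distance matrix
#'
#' Asserts symmetry, zero diagonal, entries in \[0, 1\] and dimnames.
#'
#' @param d Numeric matrix.
#' @return `d` invisibly if valid.
#' @export
validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d)) {
    stop("validation error: distance matrix must be square and numeric")
  }
  if (is.null(rownames(d))) stop("validation error: distance matrix needs dimnames")
  if (any(is.na(d))) stop("validation error: NA/NaN distance")
  if (max(abs(d - t(d))) > 1e-9) stop("validation error: distance matrix not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("validation error: nonzero diagonal")
  if (min(d) < -1e-12 || max(d) > 1 + 1e-12) {
    stop("validation error: distances must lie in [0, 1]")
  }
  invisible(d)
}
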