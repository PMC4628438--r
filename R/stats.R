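#' Pearson chi-square test of homogeneity for a contingency table
#'
#' Plain Pearson test without continuity correction: expected counts are
#' `row total x column total / grand total`, the statistic is
#' `sum((O - E)^2 / E)` with `(r - 1)(c - 1)` degrees of freedom and an
#' upper-tail chi-square p-value. Small expected counts (< 5) produce a
#' logged message, not a changed result.
#'
#' @param counts Non-negative integer matrix (e.g. isolate counts by
#'   area x crop).
#' @return A list of class `"chi2_result"` with `statistic`, `df`,
#'   `p_value`, `expected`, `method`.
#' @export
chi2_contingency <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(is.na(counts))) stop("counts must be non-negative")
  if (nrow(counts) < 2L && ncol(counts) < 2L) stop("need at least 2 rows or 2 columns")
  if (sum(counts) <= 0) stop("grand total must be positive")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("all-zero row or column: expected counts undefined")
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(res$expected < 5)) {
    message("note: ", sum(res$expected < 5), " expected cell(s) below 5")
  }
  structure(list(statistic = unname(res$statistic), df = unname(res$parameter),
                 p_value = unname(res$p.value), expected = res$expected,
                 method = "Pearson chi-square test of homogeneity"),
            class = "chi2_result")
}

#' Pearson chi-square goodness-of-fit test
#'
#' Tests observed category counts against expected probabilities
#' (uniform by default): statistic `sum((O - E)^2 / E)` with
#' `E = total x p`, `k - 1` degrees of freedom.
#'
#' @param counts Non-negative integer vector.
#' @param expected `"uniform"` or a positive probability vector summing
#'   to 1.
#' @return A `"chi2_result"` list as in [chi2_contingency()].
#' @export
chi2_goodness_of_fit <- function(counts, expected = "uniform") {
  if (any(counts < 0) || any(is.na(counts))) stop("counts must be non-negative")
  if (sum(counts) <= 0) stop("total count must be positive")
  k <- length(counts)
  if (identical(expected, "uniform")) {
    p <- rep(1 / k, k)
  } else {
    p <- expected
    if (length(p) != k) stop("expected probabilities must match counts in length")
    if (any(p <= 0)) stop("expected probabilities must be strictly positive")
    if (abs(sum(p) - 1) > 1e-9) stop("expected probabilities must sum to 1")
  }
  res <- suppressWarnings(stats::chisq.test(counts, p = p))
  structure(list(statistic = unname(res$statistic), df = unname(res$parameter),
                 p_value = unname(res$p.value), expected = sum(counts) * p,
                 method = "Pearson chi-square goodness-of-fit test"),
            class = "chi2_result")
}

#' @export
print.chi2_result <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("chi-square = %.4f; df = %d; P = %s\n", x$statistic, x$df,
              format.pval(x$p_value, digits = 4)))
  invisible(x)
}

#' Cross-tabulate isolate metadata into a contingency table
#'
#' @param metadata Metadata data.frame (see [read_isolate_metadata()]).
#' @param rows,cols Metadata columns to cross-classify (default
#'   `area` x `crop`).
#' @return An integer contingency matrix.
#' @export
cross_tabulate <- function(metadata, rows = "area", cols = "crop") {
  validate_isolate_metadata(metadata)
  tab <- table(metadata[[rows]], metadata[[cols]])
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}
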