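#' Read a binary AFLP scoring matrix
#'
#' Reads a presence/absence matrix with isolate ids in the first column
#' and locus ids in the header (or the transpose, see `transpose`).
#' Entries must be 0 or 1; anything else is a validation error reporting
#' the (row, column) coordinates.
#'
#' @param path TSV/CSV path. The delimiter is sniffed from the header
#'   line (tab preferred, then comma) unless `sep` is given.
#' @param sep Optional explicit field delimiter.
#' @param transpose If `TRUE` the file stores loci as rows and isolates
#'   as columns and is transposed after reading.
#' @return An integer matrix in \{0,1\} with isolate rownames and locus
#'   colnames, in file order.
#' @export
read_binary_matrix <- function(path, sep = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  if (is.null(sep)) {
    lines <- readLines(path, n = 50L)
    header <- lines[!startsWith(lines, "#")][1L]
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  m <- as.matrix(df)
  mode(m) <- "numeric"
  bad <- which(is.na(m) | !(m %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("validation error: non-binary entry at (row ", bad[1L, 1L],
         ", col ", bad[1L, 2L], ") of ", path,
         if (nrow(bad) > 1L) paste0(" (and ", nrow(bad) - 1L, " more)") else "")
  }
  mode(m) <- "integer"
  if (transpose) m <- t(m)
  validate_binary_matrix(m)
  m
}

#' Validate a binary profile matrix
#'
#' @param m Matrix with entries in \{0,1\}, unique isolate rownames and
#'   unique locus colnames.
#' @return `m` invisibly if valid.
#' @export
validate_binary_matrix <- function(m) {
  if (!is.matrix(m)) stop("validation error: binary profile matrix must be a matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("validation error: binary profile matrix needs isolate rownames and locus colnames")
  }
  if (anyDuplicated(rownames(m))) stop("validation error: duplicated isolate ids")
  if (anyDuplicated(colnames(m))) stop("validation error: duplicated locus ids")
  if (any(is.na(m)) || !all(m %in% c(0L, 1L))) {
    stop("validation error: matrix entries must all be 0 or 1")
  }
  invisible(m)
}

#' Write a binary AFLP scoring matrix as TSV
#'
#' @param m Binary matrix (isolates x loci).
#' @param path Output path.
#' @param header_lines Optional character vector written as `#`-prefixed
#'   comment lines before the table (provenance).
#' @export
write_binary_matrix <- function(m, path, header_lines = NULL) {
  validate_binary_matrix(m)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines) > 0L) writeLines(paste0("# ", header_lines), con)
  writeLines(paste(c("isolate_id", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(r) paste(r, collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Write a distance matrix in PHYLIP square format
#'
#' First line is the taxon count; each following row is the taxon name
#' padded to 10 characters, then the distances. Names longer than 10
#' characters are an error unless `rename` maps them to short names
#' (silent truncation would risk collisions).
#'
#' @param dm Symmetric numeric distance matrix with isolate dimnames.
#' @param path Output path.
#' @param rename Optional named character vector `c(long = "short")`
#'   applied before the 10-character check.
#' @export
write_phylip_distance <- function(dm, path, rename = NULL) {
  validate_distance_matrix(dm)
  nm <- rownames(dm)
  if (!is.null(rename)) {
    hit <- nm %in% names(rename)
    nm[hit] <- unname(rename[nm[hit]])
  }
  long <- nm[nchar(nm) > 10L]
  if (length(long) > 0L) {
    stop("PHYLIP names are limited to 10 characters; supply a renaming map for: ",
         paste(long, collapse = ", "))
  }
  if (anyDuplicated(nm)) stop("renaming map produced duplicate PHYLIP names")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(format(nrow(dm)), con)
  for (i in seq_len(nrow(dm))) {
    writeLines(paste0(formatC(nm[i], width = -10L),
                      paste(sprintf("%.6f", dm[i, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' Inverse of [write_phylip_distance()] for round-tripping and for
#' ingesting matrices written by other tools.
#'
#' @param path PHYLIP square-format file.
#' @return Symmetric numeric matrix with taxon dimnames.
#' @export
read_phylip_distance <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n) || n < 1L) stop("PHYLIP format error: bad taxon count line")
  if (length(lines) < n + 1L) stop("PHYLIP format error: fewer rows than declared taxa")
  nm <- character(n)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    row <- lines[i + 1L]
    nm[i] <- trimws(substr(row, 1L, 10L))
    vals <- as.numeric(strsplit(trimws(substring(row, 11L)), "\\s+")[[1L]])
    if (length(vals) != n) {
      stop("PHYLIP format error: row ", i, " has ", length(vals),
           " distances, expected ", n)
    }
    d[i, ] <- vals
  }
  dimnames(d) <- list(nm, nm)
  validate_distance_matrix(d)
  d
}
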