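#' CSV dialect for fragment-intensity tables
#'
#' Fragment-analysis software exports vary in delimiter and decimal mark;
#' the dialect makes both explicit instead of guessing.
#'
#' @param sep Field delimiter (default comma).
#' @param dec Decimal separator (default dot).
#' @return A list of class `"intensity_dialect"`.
#' @export
intensity_dialect <- function(sep = ",", dec = ".") {
  stopifnot(is.character(sep), nchar(sep) == 1L, is.character(dec), dec %in% c(".", ","))
  structure(list(sep = sep, dec = dec), class = "intensity_dialect")
}

.intensity_columns <- c("isolate_id", "replicate", "plate_id", "locus_id", "intensity")

#' Read a fragment-intensity table
#'
#' Reads per-band fluorescence signals (RFU), one row per isolate x
#' technical replicate x locus, with the plate each sample was run on.
#' This is the shape of a GeneMapper-style peak export after size binning:
#' `isolate_id, replicate, plate_id, locus_id, intensity`.
#'
#' Validation enforces the table invariants: non-negative intensities,
#' unique (isolate, replicate, locus) keys, replicates restricted to
#' \{1, 2\}, and identical locus sets for an isolate's two replicates.
#' Violations are reported with the file line numbers of the offending
#' rows.
#'
#' @param path Path to the delimited file.
#' @param dialect An [intensity_dialect()].
#' @return A `data.frame` with the five columns above, validated.
#' @seealso [score_matrix()] for turning intensities into presence calls.
#' @export
read_intensity_table <- function(path, dialect = intensity_dialect()) {
  if (!file.exists(path)) stop("intensity file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = dialect$sep, dec = dialect$dec,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  missing <- setdiff(.intensity_columns, names(df))
  if (length(missing) > 0L) {
    stop("intensity table format error: missing column(s) ", paste(missing, collapse = ", "))
  }
  df <- df[.intensity_columns]
  df$isolate_id <- as.character(df$isolate_id)
  df$replicate <- as.integer(df$replicate)
  df$plate_id <- as.character(df$plate_id)
  df$locus_id <- as.character(df$locus_id)
  df$intensity <- as.numeric(df$intensity)
  validate_intensity_table(df)
}

#' Validate a fragment-intensity table
#'
#' @param df A data.frame with columns
#'   `isolate_id, replicate, plate_id, locus_id, intensity`.
#' @return `df`, invisibly unchanged, if valid; otherwise an error naming
#'   the violated invariant and the offending rows (1-based data rows,
#'   i.e. file line minus the header).
#' @export
validate_intensity_table <- function(df) {
  missing <- setdiff(.intensity_columns, names(df))
  if (length(missing) > 0L) {
    stop("intensity table format error: missing column(s) ", paste(missing, collapse = ", "))
  }
  bad_rep <- which(!df$replicate %in% c(1L, 2L))
  if (length(bad_rep) > 0L) {
    stop("validation error: replicate must be 1 or 2; rows ",
         paste(utils::head(bad_rep, 10L), collapse = ", "))
  }
  bad_int <- which(is.na(df$intensity) | df$intensity < 0)
  if (length(bad_int) > 0L) {
    stop("validation error: negative or missing intensity; rows ",
         paste(utils::head(bad_int, 10L), collapse = ", "))
  }
  key <- paste(df$isolate_id, df$replicate, df$locus_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop("validation error: duplicate (isolate, replicate, locus) key(s): ",
         paste(utils::head(gsub("\r", "/", key[dup]), 5L), collapse = "; "),
         " at rows ", paste(utils::head(dup, 10L), collapse = ", "))
  }
  # each isolate must carry the same locus set in both replicates
  k1 <- split(df$locus_id[df$replicate == 1L], df$isolate_id[df$replicate == 1L])
  k2 <- split(df$locus_id[df$replicate == 2L], df$isolate_id[df$replicate == 2L])
  for (iso in union(names(k1), names(k2))) {
    odd <- c(setdiff(k1[[iso]], k2[[iso]]), setdiff(k2[[iso]], k1[[iso]]))
    if (length(odd) > 0L) {
      stop("validation error: isolate ", iso,
           " has a single replicate at locus/loci ", paste(odd, collapse = ", "))
    }
  }
  invisible(df)
}

#' Write a fragment-intensity table
#'
#' @param df Validated intensity table.
#' @param path Output path.
#' @param dialect An [intensity_dialect()].
#' @export
write_intensity_table <- function(df, path, dialect = intensity_dialect()) {
  validate_intensity_table(df)
  utils::write.table(df, path, sep = dialect$sep, dec = dialect$dec,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read isolate metadata
#'
#' Metadata has one row per isolate: sampling area, crop and origin
#' (`"study"` for isolates from the focal survey, `"external"` for
#' isolates contributed from other collections).
#'
#' @param path CSV with header `isolate_id,area,crop,origin`.
#' @return A validated `data.frame`.
#' @export
read_isolate_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_isolate_metadata(df)
}

#' Validate isolate metadata
#'
#' @param df A data.frame with columns `isolate_id`, `area`, `crop`, `origin`.
#' @return `df` invisibly if valid, else an error.
#' @export
validate_isolate_metadata <- function(df) {
  need <- c("isolate_id", "area", "crop", "origin")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("metadata format error: missing column(s) ", paste(missing, collapse = ", "))
  }
  dup <- df$isolate_id[duplicated(df$isolate_id)]
  if (length(dup) > 0L) {
    stop("validation error: duplicated metadata for isolate(s) ",
         paste(unique(dup), collapse = ", "))
  }
  invisible(df)
}

#' Write isolate metadata
#' @param df Metadata data.frame.
#' @param path Output CSV path.
#' @export
write_isolate_metadata <- function(df, path) {
  validate_isolate_metadata(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
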