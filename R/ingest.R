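#' Map externally named survey variables onto the cohort dictionary
#'
#' Renames the columns of an arbitrary survey extract to the cohort column
#' dictionary using a user-supplied mapping (cohort column -> source
#' variable name).  No source variable names are hardcoded; the caller owns
#' the mapping.  Unmapped cohort columns become `NA`; source columns not
#' mentioned in the mapping are dropped.
#'
#' @param df data frame as read from the external source.
#' @param mapping named list/vector: names are cohort columns, values are
#'   source column names.  May also be the path of a YAML file holding that
#'   mapping.
#' @return data frame with exactly the cohort dictionary columns, coerced to
#'   their documented types.
#' @export
apply_column_mapping <- function(df, mapping) {
  if (is.character(mapping) && length(mapping) == 1 && file.exists(mapping)) {
    mapping <- yaml::read_yaml(mapping)
  }
  mapping <- unlist(mapping)
  unknown <- setdiff(names(mapping), names(.cohort_columns))
  if (length(unknown)) {
    stop("mapping targets unknown cohort column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(unname(mapping), names(df))
  if (length(absent)) {
    stop("mapped source column(s) not present in data: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(row.names = seq_len(nrow(df)))
  for (cl in names(.cohort_columns)) {
    v <- if (cl %in% names(mapping)) df[[mapping[[cl]]]] else NA
    out[[cl]] <- switch(.cohort_columns[[cl]],
      integer = as.integer(v),
      numeric = as.numeric(v),
      logical = as.logical(v),
      character = as.character(v)
    )
  }
  rownames(out) <- NULL
  out
}

#' Read a cohort from a SAS transport (.xpt) file
#'
#' Thin ingestion adapter for survey releases distributed in SAS transport
#' format: reads the file with `foreign::read.xport()` and applies a
#' user-supplied variable-name mapping (see [apply_column_mapping()]).
#'
#' @param path .xpt file.
#' @param mapping mapping list or YAML file path (cohort column -> transport
#'   variable name).
#' @param provenance optional provenance list; defaults to the file path.
#' @return a [cohort()] (validation deferred to the caller when mandatory
#'   fields are unmapped).
#' @export
read_cohort_xpt <- function(path, mapping, provenance = NULL) {
  if (!requireNamespace("foreign", quietly = TRUE)) {
    stop("package 'foreign' is required to read SAS transport files", call. = FALSE)
  }
  raw <- foreign::read.xport(path)
  rec <- apply_column_mapping(raw, mapping)
  cohort(rec, provenance = provenance %||% list(source = path, seed = NA_integer_),
         validate = FALSE)
}
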