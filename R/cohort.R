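#' @keywords internal
"_PACKAGE"

## Column dictionary for a volunteer record.  One row per volunteer, keyed by
## sequence number (sqn).  Concentrations are stored in the units noted here;
## detect_* flags are FALSE when the stored value is the detection-limit
## placeholder (never zero).
.cohort_columns <- c(
  sqn             = "integer",    # unique sequence number
  gender          = "character",  # male | female
  ethnicity       = "character",  # non_hispanic_white | non_hispanic_black | mexican_american
  age             = "numeric",    # years
  bodyweight      = "numeric",    # kg
  height          = "numeric",    # cm
  void_volume     = "numeric",    # mL
  void_time       = "numeric",    # min since previous void
  ufr             = "numeric",    # mL/min, = void_volume / void_time
  urine_creatinine = "numeric",   # g/L
  osmolality      = "numeric",    # mOsm/kg
  urine_pb        = "numeric",    # ug/L
  urine_cd        = "numeric",    # ug/L
  urine_i         = "numeric",    # ug/L
  urine_as3       = "numeric",    # ug/L, arsenous acid As(III)
  urine_as5       = "numeric",    # ug/L, arsenic acid As(V)
  urine_mma       = "numeric",    # ug/L, monomethylarsonic acid
  urine_dma       = "numeric",    # ug/L, dimethylarsonic acid
  urine_total_as  = "numeric",    # ug/L, total arsenic incl. arsenobetaine
  blood_pb        = "numeric",    # ug/dL
  blood_cd        = "numeric",    # ug/L
  urinary_albumin = "numeric",    # mg/L
  serum_creatinine = "numeric",   # mg/dL
  plasma_glucose  = "numeric",    # mg/dL
  fasting_hours   = "numeric",    # h
  selfreport_diabetes = "logical",
  selfreport_ckd  = "logical",
  detect_pb       = "logical",
  detect_cd       = "logical",
  detect_i        = "logical",
  detect_as3      = "logical",
  detect_as5      = "logical",
  detect_mma      = "logical",
  detect_dma      = "logical",
  detect_total_as = "logical"
)

.concentration_columns <- c(
  "urine_creatinine", "osmolality", "urine_pb", "urine_cd", "urine_i",
  "urine_as3", "urine_as5", "urine_mma", "urine_dma", "urine_total_as",
  "blood_pb", "blood_cd"
)

#' Construct a cohort of volunteer records
#'
#' A `cohort` bundles a table of per-volunteer records with an audit trail of
#' filtering removals and a provenance tag.  The record table follows a fixed
#' column dictionary (demographics, void volume/time, urinary flow rate,
#' urine and blood chemistry, exclusion covariates and per-analyte detection
#' flags); see [read_cohort()] for the on-disk form.
#'
#' @param records data frame conforming to the column dictionary.
#' @param audit named numeric vector of records removed at each filter stage
#'   (empty for a freshly constructed cohort).
#' @param provenance list with at least `source` (free text) and `seed`
#'   (integer or `NA`); `initial_n` defaults to `nrow(records)`.
#' @param validate run [validate_cohort()] on the result.
#'
#' @return An object of class `"cohort"`: a list with elements `records`,
#'   `audit` and `provenance`.
#' @examples
#' ch <- generate_cohort(synthetic_params(n = 20, seed = 1))
#' ch
#' head(ch$records[, 1:8])
#' @export
cohort <- function(records,
                   audit = numeric(0),
                   provenance = list(source = "unknown", seed = NA_integer_),
                   validate = TRUE) {
  stopifnot(is.data.frame(records))
  if (is.null(provenance$initial_n)) {
    provenance$initial_n <- nrow(records) + sum(audit)
  }
  obj <- structure(
    list(records = records, audit = audit, provenance = provenance),
    class = "cohort"
  )
  if (validate) validate_cohort(obj)
  obj
}

#' Validate a cohort object
#'
#' Checks the structural invariants: mandatory columns present, sequence
#' numbers unique, concentrations/volumes/times/UFR strictly positive where
#' present, `ufr == void_volume / void_time` (tolerance `1e-9` relative), and
#' audit counts that reconcile with the initial record count.
#'
#' @param x a `cohort`.
#' @param tol tolerance for the UFR consistency check.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_cohort <- function(x, tol = 1e-9) {
  stopifnot(inherits(x, "cohort"))
  rec <- x$records
  missing_cols <- setdiff(names(.cohort_columns), names(rec))
  if (length(missing_cols)) {
    stop("cohort records missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(rec$sqn)) {
    stop("duplicate sqn values: ",
         paste(unique(rec$sqn[duplicated(rec$sqn)]), collapse = ", "),
         call. = FALSE)
  }
  pos_cols <- c("age", "bodyweight", "height", "void_volume", "void_time",
                "ufr", .concentration_columns)
  for (cl in pos_cols) {
    v <- rec[[cl]]
    bad <- !is.na(v) & v <= 0
    if (any(bad)) {
      stop("non-positive ", cl, " for sqn ",
           paste(rec$sqn[bad], collapse = ", "), call. = FALSE)
    }
  }
  ok <- !is.na(rec$ufr) & !is.na(rec$void_volume) & !is.na(rec$void_time)
  if (any(ok)) {
    expect <- rec$void_volume[ok] / rec$void_time[ok]
    if (any(abs(rec$ufr[ok] - expect) > tol * pmax(1, abs(expect)))) {
      stop("ufr inconsistent with void_volume/void_time", call. = FALSE)
    }
  }
  if (any(x$audit < 0)) stop("negative audit count", call. = FALSE)
  init <- x$provenance$initial_n
  if (!is.null(init) && init - sum(x$audit) != nrow(rec)) {
    stop("audit counts do not reconcile: initial ", init, " - removed ",
         sum(x$audit), " != current ", nrow(rec), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort of", nrow(x$records), "volunteer records\n")
  cat("  source:", x$provenance$source,
      if (!is.null(x$provenance$split)) paste0("[", x$provenance$split, " split]"),
      "\n")
  if (!is.na(x$provenance$seed %||% NA)) cat("  seed:  ", x$provenance$seed, "\n")
  if (length(x$audit)) {
    cat("  audit: ", x$provenance$initial_n, "initial;",
        paste(sprintf("%s -%d", names(x$audit), x$audit), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.cohort <- function(x, ...) x$records

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract urinary analyte concentrations from a cohort
#'
#' Returns the stored volume-based concentration (ug/L) for one analyte.
#' `"as_imm"` is the sum of inorganic arsenic and methylated metabolites
#' (As(III) + As(V) + MMA + DMA, arsenobetaine excluded) computed via
#' [as_imm()] under the requested non-detect policy.
#'
#' @param x a `cohort`.
#' @param analyte one of `"pb"`, `"cd"`, `"i"`, `"as_imm"`, `"creatinine"`,
#'   `"osmolality"`, `"total_as"`.
#' @param nondetect policy passed to [as_imm()] for species below detection.
#' @return numeric vector, one value per record.
#' @export
analyte_values <- function(x, analyte,
                           nondetect = c("as_is", "lod_sqrt2", "zero")) {
  stopifnot(inherits(x, "cohort"))
  nondetect <- match.arg(nondetect)
  rec <- x$records
  switch(analyte,
    pb = rec$urine_pb,
    cd = rec$urine_cd,
    i = rec$urine_i,
    total_as = rec$urine_total_as,
    creatinine = rec$urine_creatinine,
    osmolality = rec$osmolality,
    as_imm = as_imm(rec$urine_as3, rec$urine_as5, rec$urine_mma,
                    rec$urine_dma,
                    detect = cbind(rec$detect_as3, rec$detect_as5,
                                   rec$detect_mma, rec$detect_dma),
                    policy = nondetect),
    stop("unknown analyte: ", analyte, call. = FALSE)
  )
}

#' Blood concentration paired with a urinary analyte
#'
#' @inheritParams analyte_values
#' @return numeric vector (blood Pb in ug/dL, blood Cd in ug/L), or an error
#'   for analytes without a paired blood measure.
#' @export
blood_values <- function(x, analyte) {
  stopifnot(inherits(x, "cohort"))
  switch(analyte,
    pb = x$records$blood_pb,
    cd = x$records$blood_cd,
    stop("no blood measure available for analyte: ", analyte, call. = FALSE)
  )
}

## format doubles so that read.csv round-trips them bit-exactly
.format_num <- function(v) {
  out <- vapply(v, function(x) {
    if (is.na(x)) "" else sprintf("%.17g", x)
  }, character(1))
  out
}

#' Write a cohort to CSV
#'
#' One header row; columns exactly the record field names; logicals as 0/1;
#' missing values as empty cells; numeric text at full precision so that
#' `read_cohort(write_cohort(x))` reproduces every field bit-exactly.
#' UTF-8, LF line endings.
#'
#' @param x a `cohort`.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  rec <- x$records
  cols <- names(rec)
  out <- vector("list", length(cols))
  for (j in seq_along(cols)) {
    v <- rec[[j]]
    out[[j]] <- if (is.logical(v)) {
      ifelse(is.na(v), "", as.character(as.integer(v)))
    } else if (is.numeric(v) && !is.integer(v)) {
      .format_num(v)
    } else {
      ifelse(is.na(v), "", as.character(v))
    }
  }
  lines <- c(paste(cols, collapse = ","),
             do.call(paste, c(out, sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Parses a file written by [write_cohort()] (or any file conforming to the
#' column dictionary).  Under `strict = TRUE` unknown columns are rejected;
#' otherwise they are preserved verbatim.  Missing mandatory columns raise an
#' error naming the column; negative concentrations raise a validation error
#' listing the offending sequence numbers; records whose UFR disagrees with
#' `void_volume / void_time` beyond tolerance trigger one warning with the
#' mismatch count.
#'
#' @param path CSV file path.
#' @param strict reject unknown columns (`TRUE`) or carry them through.
#' @param provenance optional provenance list; defaults to the file path.
#' @return a `cohort`.
#' @export
read_cohort <- function(path, strict = TRUE, provenance = NULL) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(names(.cohort_columns), names(raw))
  if (length(missing_cols)) {
    stop("cohort file missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(raw), names(.cohort_columns))
  if (strict && length(extra)) {
    stop("unknown column(s) in cohort file: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  rec <- raw
  for (cl in names(.cohort_columns)) {
    v <- raw[[cl]]
    v[v == ""] <- NA_character_
    rec[[cl]] <- switch(.cohort_columns[[cl]],
      integer = as.integer(v),
      numeric = as.numeric(v),
      logical = as.logical(as.integer(v)),
      character = v
    )
  }
  for (cl in .concentration_columns) {
    bad <- !is.na(rec[[cl]]) & rec[[cl]] < 0
    if (any(bad)) {
      stop("negative ", cl, " for sqn ",
           paste(rec$sqn[bad], collapse = ", "), call. = FALSE)
    }
  }
  ok <- !is.na(rec$ufr) & !is.na(rec$void_volume) & !is.na(rec$void_time)
  n_bad <- 0L
  if (any(ok)) {
    expect <- rec$void_volume[ok] / rec$void_time[ok]
    n_bad <- sum(abs(rec$ufr[ok] - expect) > 1e-6 * pmax(1, abs(expect)))
    if (n_bad > 0) {
      warning(n_bad, " record(s) with ufr inconsistent with void_volume/void_time",
              call. = FALSE)
    }
  }
  cohort(rec,
         provenance = provenance %||% list(source = path, seed = NA_integer_),
         validate = n_bad == 0L)
}
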