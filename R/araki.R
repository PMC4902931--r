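#' Profile the flow-rate exponent b over a grid
#'
#' The numeric method for deriving an analyte-specific flow-rate exponent
#' from pooled spot-urine data.  On the natural-log scale the power-law
#' adjustment is linear, `ln(C * UFR^b) = ln C + b * ln UFR`, so for each
#' candidate `b` on the grid the Pearson correlation of the adjusted series
#' is computed against either
#' \describe{
#'   \item{criterion `"A"`}{`ln UFR` itself; the optimum minimises `|r|`
#'     (residual dependence of the adjusted concentration on flow rate);}
#'   \item{criterion `"B"`}{`target`, the ln blood concentration of the same
#'     analyte; the optimum maximises the signed `r` (agreement with an
#'     independent measure of internal dose).}
#' }
#' Ties are broken to the smallest `b`.  If the adjusted series is exactly
#' constant (perfect cancellation), its correlation is defined as 0.
#'
#' The correlation `r(b)` under criterion A is non-decreasing in `b`
#' (strictly increasing when `|cor(lnC, lnU)| < 1`), so the criterion-A grid
#' optimum is the grid point nearest the closed-form root
#' [closed_form_b()], clipped to the grid range.
#'
#' @param ln_conc numeric vector, ln concentrations.
#' @param ln_ufr numeric vector, ln urinary flow rates (same length).
#' @param target ln blood concentrations; required for criterion `"B"`.
#' @param criterion `"A"` or `"B"`.
#' @param grid candidate exponents; default `seq(0, 1.5, by = 0.01)`
#'   (151 points, both endpoints included).
#' @param analyte,subgroup optional labels carried into the result.
#' @return An object of class `"b_profile"`: list with `analyte`,
#'   `criterion`, `grid`, `r` (correlation at each grid point), `b_opt`,
#'   `r_opt`, `n`, `subgroup`.  Methods: `print`, `coef` (the optimum),
#'   `plot` (the sensitivity curve), `predict` (adjusted concentrations for
#'   new data).
#' @examples
#' set.seed(1)
#' u <- rnorm(200); c0 <- 1 - 0.4 * u + rnorm(200, 0, 0.3)
#' fit <- profile_b(c0, u, criterion = "A")
#' coef(fit)
#' @export
profile_b <- function(ln_conc, ln_ufr, target = NULL,
                      criterion = c("A", "B"),
                      grid = seq(0, 1.5, by = 0.01),
                      analyte = NA_character_, subgroup = NA_character_) {
  criterion <- match.arg(criterion)
  n <- length(ln_conc)
  if (length(ln_ufr) != n) stop("ln_conc and ln_ufr lengths differ", call. = FALSE)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  if (!all(is.finite(ln_conc)) || !all(is.finite(ln_ufr))) {
    stop("non-finite values in input vectors", call. = FALSE)
  }
  if (stats::sd(ln_ufr) == 0) stop("zero variance in ln_ufr", call. = FALSE)
  if (criterion == "B") {
    if (is.null(target)) stop("criterion B requires target (ln blood)", call. = FALSE)
    if (length(target) != n) stop("target length differs", call. = FALSE)
    if (!all(is.finite(target))) stop("non-finite values in target", call. = FALSE)
    if (stats::sd(target) == 0) stop("zero variance in target", call. = FALSE)
  }
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing", call. = FALSE)

  adj <- ln_conc + outer(ln_ufr, grid)              # n x length(grid)
  against <- if (criterion == "A") ln_ufr else target
  r <- suppressWarnings(as.vector(stats::cor(against, adj)))
  const <- apply(adj, 2, function(col) all(col == col[1]))
  r[const] <- 0                                     # exact-cancellation convention

  idx <- if (criterion == "A") which.min(abs(r)) else which.max(r)
  structure(
    list(analyte = analyte, criterion = criterion, grid = grid, r = r,
         b_opt = grid[idx], r_opt = r[idx], n = n, subgroup = subgroup),
    class = "b_profile"
  )
}

#' Closed-form criterion-A exponent
#'
#' The criterion-A optimum coincides with the negated ordinary-least-squares
#' slope of `ln C` on `ln UFR`: `-cov(lnC, lnU) / var(lnU)`.  Serves as the
#' analytic cross-check for the grid search.
#'
#' @inheritParams profile_b
#' @return dimensionless exponent (unclipped; may fall outside the grid).
#' @examples
#' u <- rnorm(50); closed_form_b(3 - 0.52 * u, u)  # 0.52
#' @export
closed_form_b <- function(ln_conc, ln_ufr) {
  if (stats::var(ln_ufr) == 0) stop("zero variance in ln_ufr", call. = FALSE)
  -stats::cov(ln_conc, ln_ufr) / stats::var(ln_ufr)
}

#' Fit the flow-rate exponent for one cohort analyte
#'
#' Cohort-level interface to [profile_b()]: extracts the analyte's ln
#' concentrations, ln flow rates and (for criterion B) ln blood
#' concentrations and profiles the grid.  To prevent train/test leakage the
#' fit refuses a cohort whose provenance is tagged as a testing split unless
#' `allow_testing = TRUE`.
#'
#' @param x a [cohort()], normally a training split.
#' @param analyte `"pb"`, `"cd"`, `"as_imm"`, `"i"` or `"creatinine"`.
#' @inheritParams profile_b
#' @param allow_testing permit fitting on a testing-tagged split.
#' @param nondetect non-detect policy for the AsIMM composite.
#' @return a `"b_profile"`.
#' @export
araki_b <- function(x, analyte, criterion = c("A", "B"),
                    grid = seq(0, 1.5, by = 0.01), subgroup = NA_character_,
                    allow_testing = FALSE,
                    nondetect = c("as_is", "lod_sqrt2", "zero")) {
  stopifnot(inherits(x, "cohort"))
  criterion <- match.arg(criterion)
  split_tag <- x$provenance$split
  if (!allow_testing && identical(split_tag, "testing")) {
    stop("refusing to derive b on a testing split (set allow_testing = TRUE to override)",
         call. = FALSE)
  }
  ln_c <- log(analyte_values(x, analyte, nondetect = match.arg(nondetect)))
  ln_u <- log(x$records$ufr)
  target <- if (criterion == "B") log(blood_values(x, analyte))
  profile_b(ln_c, ln_u, target = target, criterion = criterion, grid = grid,
            analyte = analyte, subgroup = subgroup)
}

#' @export
print.b_profile <- function(x, ...) {
  cat(sprintf("Flow-rate exponent profile: analyte %s, criterion %s%s\n",
              x$analyte, x$criterion,
              if (!is.na(x$subgroup)) paste0(", subgroup ", x$subgroup) else ""))
  cat(sprintf("  grid [%g, %g] step %g, n = %d\n",
              min(x$grid), max(x$grid), x$grid[2] - x$grid[1], x$n))
  cat(sprintf("  b_opt = %.2f  (r at optimum = %.4f)\n", x$b_opt, x$r_opt))
  invisible(x)
}

#' @export
coef.b_profile <- function(object, ...) c(b = object$b_opt)

#' @export
summary.b_profile <- function(object, ...) {
  structure(list(profile = object), class = "summary.b_profile")
}

#' @export
print.summary.b_profile <- function(x, ...) {
  print(x$profile)
  p <- x$profile
  nb <- which(p$grid == p$b_opt)
  lo <- max(1, nb - 1); hi <- min(length(p$grid), nb + 1)
  cat("  neighbouring grid correlations:",
      paste(sprintf("r(%.2f)=%.4f", p$grid[lo:hi], p$r[lo:hi]), collapse = "  "),
      "\n")
  invisible(x)
}

#' @export
plot.b_profile <- function(x, ...) {
  ylab <- if (x$criterion == "A") "r (adjusted vs ln UFR)" else "r (adjusted vs ln blood)"
  graphics::plot(x$grid, x$r, type = "l", xlab = "Araki's b", ylab = ylab,
                 main = sprintf("%s, criterion %s", x$analyte, x$criterion), ...)
  graphics::abline(h = 0, lty = 3)
  graphics::points(x$b_opt, x$r_opt, pch = 18, cex = 1.4)
  invisible(x)
}

#' @export
predict.b_profile <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "cohort"))
  cv <- analyte_values(newdata, object$analyte)
  ufr_power_adjust(cv, newdata$records$ufr, object$b_opt)
}

.default_age_bands <- data.frame(
  band = c("6-11", "12-19", "20-39", "40-59", ">60"),
  lo = c(6, 12, 20, 40, 60),
  hi = c(11, 19, 39, 59, Inf)
)

.age_band_of <- function(age, bands = .default_age_bands) {
  yrs <- floor(age)                     # band membership by completed years
  out <- rep(NA_character_, length(age))
  for (i in seq_len(nrow(bands))) {
    sel <- yrs >= bands$lo[i] & yrs <= bands$hi[i]
    out[sel] <- bands$band[i]
  }
  out
}

.subgroup_labels <- function(x, grouping, age_bands = .default_age_bands) {
  rec <- x$records
  switch(grouping,
    none = rep("all", nrow(rec)),
    gender_ethnicity = paste(rec$ethnicity, rec$gender, sep = "."),
    age_band = .age_band_of(rec$age, age_bands),
    stop("unknown grouping: ", grouping, call. = FALSE)
  )
}

#' Derive flow-rate exponents, optionally per demographic subgroup
#'
#' Runs [araki_b()] on the whole cohort (`grouping = "none"`) or on each
#' gender-by-ethnicity cell or age band, returning a table of optima.  For
#' criterion A the p-value of the `ln C ~ ln UFR` regression slope is
#' reported per subgroup, since an insignificant slope warns that the
#' subgroup's optimum reflects sampling noise rather than dilution
#' physiology.  Subgroups smaller than `min_n` are skipped with a warning.
#'
#' @inheritParams araki_b
#' @param analytes analyte keys to profile.
#' @param grouping `"none"`, `"gender_ethnicity"` or `"age_band"`.
#' @param age_bands data frame with `band`, `lo`, `hi` columns.
#' @param min_n minimum subgroup size (default 4).
#' @return data frame of class `"b_table"` with columns `analyte`,
#'   `subgroup`, `criterion`, `b_opt`, `r_opt`, `n`, `slope_p`; its
#'   `"split"` attribute records the provenance split tag of `x`.
#' @export
derive_b <- function(x, analytes = c("pb", "cd", "as_imm", "i"),
                     criterion = c("A", "B"),
                     grouping = c("none", "gender_ethnicity", "age_band"),
                     grid = seq(0, 1.5, by = 0.01),
                     age_bands = .default_age_bands,
                     min_n = 4, allow_testing = FALSE) {
  stopifnot(inherits(x, "cohort"))
  criterion <- match.arg(criterion)
  grouping <- match.arg(grouping)
  labels <- .subgroup_labels(x, grouping, age_bands)
  groups <- if (grouping == "age_band") {
    intersect(age_bands$band, unique(labels))
  } else sort(unique(labels))

  rows <- list()
  for (g in groups) {
    sel <- which(labels == g)
    if (length(sel) < min_n) {
      warning("subgroup '", g, "' skipped: n = ", length(sel), " < ", min_n,
              call. = FALSE)
      next
    }
    sub <- x
    sub$records <- x$records[sel, , drop = FALSE]
    rownames(sub$records) <- NULL
    sub$audit <- numeric(0)
    sub$provenance$initial_n <- length(sel)
    for (an in analytes) {
      fit <- araki_b(sub, an, criterion = criterion, grid = grid,
                     subgroup = g, allow_testing = allow_testing)
      ln_c <- log(analyte_values(sub, an))
      ln_u <- log(sub$records$ufr)
      slope_p <- if (criterion == "A") {
        summary(stats::lm(ln_c ~ ln_u))$coefficients["ln_u", "Pr(>|t|)"]
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = an, subgroup = g, criterion = criterion,
        b_opt = fit$b_opt, r_opt = fit$r_opt, n = fit$n, slope_p = slope_p,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(analyte = character(0), subgroup = character(0),
               criterion = character(0), b_opt = numeric(0),
               r_opt = numeric(0), n = integer(0), slope_p = numeric(0))
  attr(out, "split") <- x$provenance$split %||% x$provenance$source
  class(out) <- c("b_table", "data.frame")
  out
}

#' Apply derived exponents across a cohort
#'
#' Dispatches the flow-rate power-law adjustment with the matching exponent
#' per record: a single group-wide `b` per analyte (`mode = "global"`) or
#' the exponent of each record's demographic subgroup
#' (`mode = "per_subgroup"`).
#'
#' @param x a [cohort()].
#' @param b_table a `"b_table"` from [derive_b()].
#' @param mode `"global"` or `"per_subgroup"`.
#' @param grouping subgroup scheme used when `mode = "per_subgroup"`; must
#'   match the one used to derive `b_table`.
#' @param analytes analytes to adjust (default: those present in `b_table`).
#' @param age_bands age-band definitions for `grouping = "age_band"`.
#' @return an `"adjustment_result"` data frame (see [adjust_cohort()]).
#' @export
apply_b <- function(x, b_table, mode = c("global", "per_subgroup"),
                    grouping = c("none", "gender_ethnicity", "age_band"),
                    analytes = NULL, age_bands = .default_age_bands) {
  stopifnot(inherits(x, "cohort"), is.data.frame(b_table))
  mode <- match.arg(mode)
  grouping <- match.arg(grouping)
  analytes <- analytes %||% unique(b_table$analyte)
  rec <- x$records
  out <- lapply(analytes, function(an) {
    bt <- b_table[b_table$analyte == an, , drop = FALSE]
    if (!nrow(bt)) stop("b_table has no entry for analyte ", an, call. = FALSE)
    cv <- analyte_values(x, an)
    if (mode == "global") {
      if (nrow(bt) > 1) bt <- bt[bt$subgroup == "all", , drop = FALSE]
      if (nrow(bt) != 1) stop("global mode needs a single b for ", an, call. = FALSE)
      b_rec <- rep(bt$b_opt, nrow(rec))
    } else {
      labels <- .subgroup_labels(x, grouping, age_bands)
      b_rec <- bt$b_opt[match(labels, bt$subgroup)]
      if (anyNA(b_rec)) {
        stop("no b value for subgroup(s): ",
             paste(unique(labels[is.na(b_rec)]), collapse = ", "),
             call. = FALSE)
      }
    }
    data.frame(sqn = rec$sqn, analyte = an, method = "ufr_power",
               value = ufr_power_adjust(cv, rec$ufr, b_rec),
               units = "ug/L at UFR 1 mL/min", b_used = b_rec,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("adjustment_result", "data.frame")
  res
}
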