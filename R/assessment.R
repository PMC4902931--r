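#' Partition a cohort into training and testing splits
#'
#' Simple random sampling without replacement: `round(fraction * n)` records
#' (round-half-even, R's `round`) form the training split used to derive
#' flow-rate exponents; the remainder form the testing split on which
#' adjustment performance is assessed.
#'
#' @param x a [cohort()].
#' @param fraction training proportion in (0, 1); default 0.8.
#' @param seed integer seed; the same seed reproduces the same split.
#' @return An object of class `"cohort_split"`: list with `training_sqns`,
#'   `testing_sqns`, `fraction`, `seed`.
#' @examples
#' ch <- generate_cohort(synthetic_params(n = 100, seed = 1))
#' sp <- split_cohort(ch, seed = 1)
#' length(sp$training_sqns)  # 80
#' @export
split_cohort <- function(x, fraction = 0.8, seed = 1L) {
  stopifnot(inherits(x, "cohort"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)", call. = FALSE)
  n <- nrow(x$records)
  n_train <- round(fraction * n)
  if (n_train < 2 || n - n_train < 2) {
    stop("cohort too small to give both splits at least 2 records", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  train_idx <- sort(sample.int(n, n_train))
  structure(
    list(training_sqns = x$records$sqn[train_idx],
         testing_sqns = x$records$sqn[-train_idx],
         fraction = fraction, seed = as.integer(seed)),
    class = "cohort_split"
  )
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("Cohort split: %d training / %d testing (fraction %.2f, seed %d)\n",
              length(x$training_sqns), length(x$testing_sqns),
              x$fraction, x$seed))
  invisible(x)
}

#' Materialise the two halves of a split
#'
#' @param x the [cohort()] that was split.
#' @param split a `"cohort_split"` from [split_cohort()].
#' @return list with `training` and `testing` cohorts, each carrying a
#'   `split` provenance tag consumed by the leakage guards in [araki_b()]
#'   and [evaluate_methods()].
#' @export
apply_split <- function(x, split) {
  stopifnot(inherits(x, "cohort"), inherits(split, "cohort_split"))
  take <- function(sqns, tag) {
    sub <- x
    sub$records <- x$records[match(sqns, x$records$sqn), , drop = FALSE]
    rownames(sub$records) <- NULL
    sub$audit <- numeric(0)
    sub$provenance$initial_n <- length(sqns)
    sub$provenance$split <- tag
    sub
  }
  list(training = take(split$training_sqns, "training"),
       testing = take(split$testing_sqns, "testing"))
}

#' Geometric mean
#'
#' `exp(mean(ln x))`; the summary of choice for positively skewed
#' concentration data.
#'
#' @param x positive numeric vector.
#' @return the geometric mean (scalar).
#' @examples
#' geometric_mean(c(1, 10, 100))  # 10
#' @export
geometric_mean <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("geometric mean requires strictly positive finite values", call. = FALSE)
  }
  exp(mean(log(x)))
}

#' Pearson correlation on ln-transformed data
#'
#' Computes `r` between `ln x` and `ln y`, a two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, and a
#' 95% confidence interval via the Fisher z transform
#' (`atanh(r) +/- 1.96 / sqrt(n - 3)`, back-transformed).  Because the
#' inputs are logged, the result is invariant to multiplicative unit
#' changes, so e.g. blood Pb in ug/dL needs no conversion against urine in
#' ug/L.
#'
#' @param x,y positive numeric vectors of equal length, n >= 4.
#' @return list of class `"ln_pearson"`: `r`, `ci_low`, `ci_high`,
#'   `p_value`, `n`, `degenerate` (`TRUE` when `|r| = 1`, in which case the
#'   interval collapses and the p-value underflows).
#' @export
ln_pearson <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ", call. = FALSE)
  if (n < 4) stop("need at least 4 observations", call. = FALSE)
  if (any(x <= 0) || any(y <= 0)) stop("values must be > 0 before logging", call. = FALSE)
  lx <- log(x); ly <- log(y)
  if (stats::sd(lx) == 0 || stats::sd(ly) == 0) {
    stop("zero variance after ln transform", call. = FALSE)
  }
  r <- stats::cor(lx, ly)
  degenerate <- abs(r) >= 1 - 1e-15
  if (degenerate) {
    p <- 0
    ci <- c(r, r)
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    z <- atanh(r)
    ci <- tanh(z + c(-1, 1) * 1.96 / sqrt(n - 3))
  }
  structure(list(r = r, ci_low = ci[1], ci_high = ci[2], p_value = p,
                 n = n, degenerate = degenerate),
            class = "ln_pearson")
}

#' @export
print.ln_pearson <- function(x, ...) {
  cat(sprintf("ln-scale Pearson r = %.3f (95%% CI %.3f, %.3f), p = %.3g, n = %d\n",
              x$r, x$ci_low, x$ci_high, x$p_value, x$n))
  invisible(x)
}

#' Williams's test for two dependent correlations sharing a variable
#'
#' Tests whether `r12` and `r13` (the correlations of variables 2 and 3 with
#' the common variable 1) differ, accounting for their dependence through
#' `r23`.  The Hotelling-Williams statistic is
#' `t = (r12 - r13) * sqrt((n - 1) * (1 + r23) /
#'   (2 * detR * (n - 1)/(n - 3) + rbar^2 * (1 - r23)^3))`
#' with `detR = 1 - r12^2 - r13^2 - r23^2 + 2 r12 r13 r23`,
#' `rbar = (r12 + r13)/2`, on `n - 3` degrees of freedom (two-sided).
#' It is antisymmetric: swapping `r12` and `r13` negates `t`.
#'
#' @param r12,r13 correlations of the two competitors with the common
#'   variable, each in (-1, 1).
#' @param r23 correlation between the competitors, in (-1, 1).
#' @param n sample size, >= 4.
#' @return An object of class `"htest"` with `statistic` (t), `parameter`
#'   (df = n - 3) and `p.value`.
#' @examples
#' williams_test(0.8, 0.6, 0.5, 100)
#' @export
williams_test <- function(r12, r13, r23, n) {
  if (n <= 3) stop("n must be at least 4", call. = FALSE)
  if (any(abs(c(r12, r13, r23)) >= 1)) {
    stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)
  }
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR < -1e-12) {
    stop("correlation triple is not positive semidefinite (det R < 0)", call. = FALSE)
  }
  detR <- max(detR, 0)
  rbar <- (r12 + r13) / 2
  tstat <- (r12 - r13) *
    sqrt((n - 1) * (1 + r23) /
           (2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r23)^3))
  df <- n - 3
  p <- 2 * stats::pt(-abs(tstat), df = df)
  structure(
    list(statistic = c(t = tstat), parameter = c(df = df), p.value = p,
         estimate = c(r12 = r12, r13 = r13, r23 = r23),
         method = "Williams's test for two dependent correlations sharing a variable",
         data.name = sprintf("r12 = %.3f, r13 = %.3f, r23 = %.3f, n = %d",
                             r12, r13, r23, as.integer(n))),
    class = "htest"
  )
}

#' Compact letter display from a pairwise significance pattern
#'
#' Insert-and-absorb algorithm: starting from one group holding every item,
#' each significantly different pair splits any group containing both into
#' two copies (one without each member); groups that become subsets of
#' others are absorbed.  The resulting display never lets a significant
#' pair share a letter and never separates a non-significant pair entirely.
#' Letters are assigned to groups in the order of `order` (best item
#' first).
#'
#' @param signif logical symmetric matrix; `TRUE` where the pair differs
#'   significantly.  Row/column names label the items.
#' @param order optional character vector giving the item ordering used for
#'   letter assignment (default: row-name order).
#' @return named character vector of letter strings, one per item.
#' @examples
#' m <- matrix(FALSE, 3, 3, dimnames = list(c("a1","a2","a3"), c("a1","a2","a3")))
#' m["a1", "a3"] <- m["a3", "a1"] <- TRUE
#' compact_letters(m)
#' @export
compact_letters <- function(signif, order = NULL) {
  items <- rownames(signif)
  if (is.null(items)) stop("signif matrix needs row names", call. = FALSE)
  order <- order %||% items
  stopifnot(setequal(order, items))

  groups <- list(items)
  for (i in seq_along(items)) {
    for (j in seq_along(items)) {
      if (j <= i || !signif[items[i], items[j]]) next
      pair <- items[c(i, j)]
      new_groups <- list()
      for (g in groups) {
        if (all(pair %in% g)) {
          new_groups <- c(new_groups, list(setdiff(g, pair[1])),
                          list(setdiff(g, pair[2])))
        } else {
          new_groups <- c(new_groups, list(g))
        }
      }
      ## absorb groups that are subsets of another; drop duplicates
      keep <- rep(TRUE, length(new_groups))
      for (a in seq_along(new_groups)) {
        for (b in seq_along(new_groups)) {
          if (a == b || !keep[a]) next
          if (all(new_groups[[a]] %in% new_groups[[b]]) &&
              (length(new_groups[[a]]) < length(new_groups[[b]]) || a > b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      groups <- new_groups[keep]
      groups <- groups[lengths(groups) > 0]
    }
  }
  ## order groups by the position of their best member, then assign letters
  pos <- vapply(groups, function(g) min(match(g, order)), numeric(1))
  groups <- groups[base::order(pos)]
  out <- stats::setNames(rep("", length(items)), items)
  for (k in seq_along(groups)) {
    for (m in groups[[k]]) out[m] <- paste0(out[m], letters[k])
  }
  out[order]
}

#' Letter groups for a family of dependent correlations
#'
#' Given each method's correlation with a common variable and the pairwise
#' correlations between the methods' adjusted series, runs all pairwise
#' Williams's tests at level `alpha` and converts the significance pattern
#' into a compact letter display.  Methods are lettered best-first:
#' smallest `|r|` for criterion A (`better = "low"`), largest `r` for
#' criterion B (`better = "high"`).
#'
#' @param r_common named numeric vector: each method's correlation with the
#'   common variable.
#' @param r_between numeric matrix of correlations between the methods'
#'   series (dimnames matching `names(r_common)`).
#' @param n shared sample size.
#' @param alpha significance level for the pairwise tests.
#' @param better `"low"` (criterion A, magnitude closer to zero is better)
#'   or `"high"` (criterion B).
#' @return named character vector of letters in the order of `r_common`.
#' @export
letter_groups <- function(r_common, r_between, n, alpha = 0.05,
                          better = c("high", "low")) {
  better <- match.arg(better)
  methods <- names(r_common)
  stopifnot(!is.null(methods), all(methods %in% rownames(r_between)))
  k <- length(methods)
  signif <- matrix(FALSE, k, k, dimnames = list(methods, methods))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      r23 <- r_between[methods[i], methods[j]]
      ## numerically identical series (e.g. two grids landing on the same
      ## exponent) are never significantly different
      if (abs(r23) >= 1 - 1e-12 &&
          abs(r_common[[i]] - r_common[[j]]) < 1e-12) next
      w <- williams_test(r_common[[i]], r_common[[j]], r23, n)
      signif[i, j] <- signif[j, i] <- w$p.value < alpha
    }
  }
  ord <- if (better == "low") methods[base::order(abs(r_common))]
         else methods[base::order(-r_common)]
  compact_letters(signif, order = ord)[methods]
}

## ln-scale adjusted series for one analyte under every method.
## ER/ERBW enter as ln(ER) = ln C + ln UFR + const so that all methods are
## compared on the same ln-correlation footing; constants do not move r.
.ln_adjusted_series <- function(x, analyte, b_A = NA, b_B = NA, osm_ref) {
  rec <- x$records
  ln_c <- log(analyte_values(x, analyte))
  ln_u <- log(rec$ufr)
  out <- list(
    unadjusted = ln_c,
    creatinine = ln_c - log(rec$urine_creatinine),
    osmolality = ln_c + log(osm_ref) - log(rec$osmolality),
    er = ln_c + ln_u + log(60),
    erbw = ln_c + ln_u + log(60) - log(rec$bodyweight)
  )
  if (!is.na(b_A)) out$ufra <- ln_c + b_A * ln_u
  if (!is.na(b_B)) out$ufrb <- ln_c + b_B * ln_u
  out
}

#' Assess adjustment-method performance on a testing split
#'
#' For every analyte and adjustment method, computes the ln-scale Pearson
#' correlation of the adjusted concentration with urinary flow rate
#' (criterion A: weaker is better) and, for analytes with a paired blood
#' measure, with the blood concentration (criterion B: stronger is better).
#' Within each analyte-criterion family, pairwise Williams's tests produce
#' a compact letter display (methods share a letter when not significantly
#' different) and methods are ranked best-first.
#'
#' The exponent table must come from a training split: a `b_table` whose
#' provenance is tagged `"testing"` is refused.
#'
#' @param testing a testing-split [cohort()].
#' @param b_table a `"b_table"` from [derive_b()] on the training split,
#'   containing criterion-A rows and (for blood-paired analytes)
#'   criterion-B rows.
#' @param osm_ref reference osmolality (mOsm/kg), normally the training
#'   median.
#' @param analytes analytes to assess.
#' @param blood_analytes analytes with a paired blood measure (criterion B).
#' @param alpha significance level for the letter display.
#' @return data frame of class `"method_assessment"`: `criterion`,
#'   `analyte`, `method`, `r`, `ci_low`, `ci_high`, `p`, `n`, `letters`,
#'   `rank`.
#' @export
evaluate_methods <- function(testing, b_table, osm_ref,
                             analytes = c("pb", "cd", "as_imm", "i"),
                             blood_analytes = c("pb", "cd"),
                             alpha = 0.05) {
  stopifnot(inherits(testing, "cohort"), is.data.frame(b_table))
  if (identical(attr(b_table, "split"), "testing")) {
    stop("b_table was derived on a testing split; refusing to evaluate (leakage)",
         call. = FALSE)
  }
  get_b <- function(an, crit) {
    row <- b_table[b_table$analyte == an & b_table$criterion == crit &
                     b_table$subgroup == "all", , drop = FALSE]
    if (nrow(row)) row$b_opt[1] else NA_real_
  }
  rows <- list()
  for (an in analytes) {
    b_A <- get_b(an, "A")
    b_B <- if (an %in% blood_analytes) get_b(an, "B") else NA_real_
    series <- .ln_adjusted_series(testing, an, b_A = b_A, b_B = b_B, osm_ref)
    n <- nrow(testing$records)
    ln_u <- log(testing$records$ufr)
    mat <- do.call(cbind, series)
    r_between <- stats::cor(mat)

    crits <- list(A = ln_u)
    if (an %in% blood_analytes) crits$B <- log(blood_values(testing, an))
    for (crit in names(crits)) {
      common <- crits[[crit]]
      use <- names(series)
      if (crit == "B" && is.na(b_B)) use <- setdiff(use, "ufrb")
      r_common <- vapply(series[use], function(s) stats::cor(s, common), numeric(1))
      rep_core <- lapply(series[use], function(s) {
        lp <- ln_pearson(exp(s), exp(common))
        c(lp$ci_low, lp$ci_high, lp$p_value)
      })
      letters_ <- letter_groups(r_common, r_between[use, use, drop = FALSE],
                                n = n, alpha = alpha,
                                better = if (crit == "A") "low" else "high")
      score <- if (crit == "A") abs(r_common) else -r_common
      rk <- rank(score, ties.method = "min")
      for (m in use) {
        rows[[length(rows) + 1L]] <- data.frame(
          criterion = crit, analyte = an, method = m,
          r = r_common[[m]],
          ci_low = rep_core[[m]][1], ci_high = rep_core[[m]][2],
          p = rep_core[[m]][3], n = n,
          letters = letters_[[m]], rank = rk[[m]],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("method_assessment", "data.frame")
  out
}

#' @export
print.method_assessment <- function(x, ...) {
  df <- as.data.frame(x)
  for (crit in unique(df$criterion)) {
    cat(sprintf("Criterion %s (%s):\n", crit,
                if (crit == "A") "adjusted vs UFR; |r| closer to 0 is better"
                else "adjusted vs blood; larger r is better"))
    sub <- df[df$criterion == crit, ]
    for (an in unique(sub$analyte)) {
      cat(" ", an, "\n")
      ss <- sub[sub$analyte == an, ]
      ss <- ss[order(ss$rank), ]
      for (i in seq_len(nrow(ss))) {
        cat(sprintf("    %-10s r = %6.3f (%6.3f, %6.3f)  p = %-8.2g %s\n",
                    ss$method[i], ss$r[i], ss$ci_low[i], ss$ci_high[i],
                    ss$p[i], ss$letters[i]))
      }
    }
  }
  invisible(x)
}

#' Geometric means and ranges of adjusted concentrations
#'
#' Summary table in the style of a methods-comparison report: one row per
#' analyte, one column block per adjustment method, each cell the geometric
#' mean with the (min, max) range.
#'
#' @inheritParams evaluate_methods
#' @param x a [cohort()] (typically the testing split).
#' @return data frame with columns `analyte`, `method`, `units`, `gm`,
#'   `min`, `max`.
#' @export
adjustment_gm_table <- function(x, b_table, osm_ref,
                                analytes = c("pb", "cd", "as_imm", "i"),
                                blood_analytes = c("pb", "cd")) {
  stopifnot(inherits(x, "cohort"))
  get_b <- function(an, crit) {
    row <- b_table[b_table$analyte == an & b_table$criterion == crit &
                     b_table$subgroup == "all", , drop = FALSE]
    if (nrow(row)) row$b_opt[1] else NA_real_
  }
  rows <- list()
  for (an in analytes) {
    for (m in c("unadjusted", "creatinine", "osmolality", "er", "erbw")) {
      adj <- adjust_cohort(x, m, analytes = an, osm_ref = osm_ref)
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = an, method = m, units = adj$units[1],
        gm = geometric_mean(adj$value),
        min = min(adj$value), max = max(adj$value),
        stringsAsFactors = FALSE)
    }
    for (crit in c("A", "B")) {
      bb <- get_b(an, crit)
      if (is.na(bb) || (crit == "B" && !an %in% blood_analytes)) next
      adj <- adjust_cohort(x, "ufr_power", analytes = an,
                           b = stats::setNames(bb, an))
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = an, method = paste0("ufr", tolower(crit)),
        units = adj$units[1],
        gm = geometric_mean(adj$value),
        min = min(adj$value), max = max(adj$value),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
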