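#' Estimated glomerular filtration rate (CKD-EPI 2009)
#'
#' The 2009 CKD-EPI creatinine equation for adults:
#' `141 * min(Scr/k, 1)^alpha * max(Scr/k, 1)^-1.209 * 0.993^age *
#' (1.018 if female) * (1.159 if non-Hispanic black)`, with `k = 0.7`
#' (female) / `0.9` (male) and `alpha = -0.329` (female) / `-0.411` (male).
#' The race coefficient is retained as historically faithful to the
#' three-ethnicity survey designs this package targets; it is not current
#' clinical practice.
#'
#' @param serum_creatinine mg/dL, > 0.
#' @param age years; the equation is intended for age >= 18 (use
#'   [egfr_schwartz()] for children).
#' @param gender `"male"` or `"female"`.
#' @param ethnicity ethnicity label; `"non_hispanic_black"` applies the
#'   1.159 coefficient.
#' @return eGFR in mL/min/1.73 m^2 (vectorized).
#' @examples
#' egfr_ckd_epi(1.0, 50, "male", "non_hispanic_white")  # ~87.4
#' @export
egfr_ckd_epi <- function(serum_creatinine, age, gender, ethnicity) {
  if (any(serum_creatinine <= 0)) stop("serum_creatinine must be > 0", call. = FALSE)
  if (any(age < 18)) {
    warning("CKD-EPI is intended for age >= 18; use egfr_schwartz() for children",
            call. = FALSE)
  }
  female <- gender == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  ratio <- serum_creatinine / kappa
  141 * pmin(ratio, 1)^alpha * pmax(ratio, 1)^-1.209 * 0.993^age *
    ifelse(female, 1.018, 1) *
    ifelse(ethnicity == "non_hispanic_black", 1.159, 1)
}

#' Estimated glomerular filtration rate (Bedside Schwartz)
#'
#' `0.413 * height / Scr`, intended for volunteers aged under 18.
#'
#' @param height cm, > 0.
#' @param serum_creatinine mg/dL, > 0.
#' @return eGFR in mL/min/1.73 m^2 (vectorized).
#' @examples
#' egfr_schwartz(140, 0.5)  # 115.64
#' @export
egfr_schwartz <- function(height, serum_creatinine) {
  if (any(height <= 0) || any(serum_creatinine <= 0)) {
    stop("height and serum_creatinine must be > 0", call. = FALSE)
  }
  0.413 * height / serum_creatinine
}

#' Albuminuria flag
#'
#' Albuminuria is a urinary albumin-creatinine ratio strictly greater than
#' 30 mg/g creatinine.  With albumin in mg/L and creatinine in g/L the ratio
#' is mg/g directly.
#'
#' @param urinary_albumin mg/L.
#' @param urine_creatinine g/L, > 0.
#' @return logical vector.
#' @export
flag_albuminuria <- function(urinary_albumin, urine_creatinine) {
  if (any(urine_creatinine <= 0, na.rm = TRUE)) {
    stop("urine_creatinine must be > 0 (albumin-creatinine ratio undefined)",
         call. = FALSE)
  }
  urinary_albumin / urine_creatinine > 30
}

#' Diabetes flag
#'
#' Diabetes is a self-reported physician diagnosis, or plasma glucose
#' >= 126 mg/dL after >= 8 h fasting, or >= 200 mg/dL with < 8 h fasting
#' (both thresholds inclusive).
#'
#' @param selfreport logical.
#' @param plasma_glucose mg/dL; may be `NA`.
#' @param fasting_hours hours since last food; may be `NA`.
#' @return logical vector; missing glucose with `selfreport = FALSE` gives
#'   `FALSE` (the laboratory arm is unevaluable).
#' @export
flag_diabetes <- function(selfreport, plasma_glucose, fasting_hours) {
  lab <- ifelse(is.na(plasma_glucose) | is.na(fasting_hours), FALSE,
                ifelse(fasting_hours >= 8, plasma_glucose >= 126,
                       plasma_glucose >= 200))
  selfreport | lab
}

#' Chronic kidney disease flag
#'
#' CKD is a self-reported diagnosis or an eGFR strictly below
#' 60 mL/min/1.73 m^2.
#'
#' @param selfreport logical.
#' @param egfr mL/min/1.73 m^2; may be `NA`.
#' @return logical vector.
#' @export
flag_ckd <- function(selfreport, egfr) {
  selfreport | (!is.na(egfr) & egfr < 60)
}

#' Apply the eligibility exclusion cascade
#'
#' Stage 1 removes volunteers with evidence of albuminuria, diabetes or
#' chronic kidney disease (eGFR by CKD-EPI for age >= 18, Bedside Schwartz
#' otherwise).  Stage 2 removes volunteers lacking a detected concentration
#' for any of urinary Pb, Cd, total As or I (limiting the effect of
#' censoring on downstream correlation analyses).  Every removal is recorded
#' with its triggering rule(s).
#'
#' @param x a [cohort()].
#' @param strict if `TRUE`, a record missing a covariate required by a rule
#'   is an error naming the sqn and field; if `FALSE` such records are
#'   dropped with reason `"missing:<field>"`.
#' @return list with elements `cohort` (the filtered cohort, audit updated)
#'   and `audits` (a list of `exclusion_audit` objects, one per stage, each
#'   with `stage`, `removed`, `remaining` and per-sqn `reasons`).
#' @examples
#' ch <- generate_cohort(synthetic_params(n = 300, seed = 7))
#' res <- apply_exclusions(ch)
#' res$cohort$audit
#' @export
apply_exclusions <- function(x, strict = TRUE) {
  stopifnot(inherits(x, "cohort"))
  rec <- x$records
  n0 <- nrow(rec)

  required <- c("urinary_albumin", "urine_creatinine", "selfreport_diabetes",
                "plasma_glucose", "fasting_hours", "selfreport_ckd",
                "serum_creatinine", "age", "gender", "ethnicity", "height")
  miss_reason <- vector("list", n0)
  for (cl in required) {
    bad <- which(is.na(rec[[cl]]))
    if (length(bad)) {
      if (strict) {
        stop("record sqn ", rec$sqn[bad[1]], " missing required field ",
             cl, call. = FALSE)
      }
      for (i in bad) miss_reason[[i]] <- c(miss_reason[[i]], paste0("missing:", cl))
    }
  }
  evaluable <- lengths(miss_reason) == 0

  reasons <- vector("list", n0)
  if (any(evaluable)) {
    ev <- which(evaluable)
    alb <- flag_albuminuria(rec$urinary_albumin[ev], rec$urine_creatinine[ev])
    dia <- flag_diabetes(rec$selfreport_diabetes[ev], rec$plasma_glucose[ev],
                         rec$fasting_hours[ev])
    adult <- rec$age[ev] >= 18
    egfr <- numeric(length(ev))
    if (any(adult)) {
      egfr[adult] <- egfr_ckd_epi(rec$serum_creatinine[ev][adult],
                                  rec$age[ev][adult], rec$gender[ev][adult],
                                  rec$ethnicity[ev][adult])
    }
    if (any(!adult)) {
      egfr[!adult] <- egfr_schwartz(rec$height[ev][!adult],
                                    rec$serum_creatinine[ev][!adult])
    }
    ckd <- flag_ckd(rec$selfreport_ckd[ev], egfr)
    for (k in seq_along(ev)) {
      r <- c(if (alb[k]) "albuminuria", if (dia[k]) "diabetes",
             if (ckd[k]) "ckd")
      if (length(r)) reasons[[ev[k]]] <- r
    }
  }
  for (i in which(!evaluable)) reasons[[i]] <- miss_reason[[i]]

  drop1 <- lengths(reasons) > 0
  audit1 <- structure(
    list(stage = "albuminuria_diabetes_ckd",
         removed = sum(drop1), remaining = n0 - sum(drop1),
         reasons = stats::setNames(reasons[drop1], rec$sqn[drop1])),
    class = "exclusion_audit"
  )
  rec1 <- rec[!drop1, , drop = FALSE]
  rownames(rec1) <- NULL

  detected <- rec1$detect_pb & rec1$detect_cd & rec1$detect_total_as &
    rec1$detect_i
  nd_reason <- lapply(seq_len(nrow(rec1)), function(i) {
    if (detected[i]) character(0) else {
      paste0("nondetect:", c("pb", "cd", "total_as", "i")[
        !c(rec1$detect_pb[i], rec1$detect_cd[i], rec1$detect_total_as[i],
           rec1$detect_i[i])])
    }
  })
  drop2 <- !detected
  audit2 <- structure(
    list(stage = "nondetect",
         removed = sum(drop2), remaining = nrow(rec1) - sum(drop2),
         reasons = stats::setNames(nd_reason[drop2], rec1$sqn[drop2])),
    class = "exclusion_audit"
  )
  rec2 <- rec1[detected, , drop = FALSE]
  rownames(rec2) <- NULL

  out <- x
  out$records <- rec2
  out$audit <- c(x$audit,
                 albuminuria_diabetes_ckd = audit1$removed,
                 nondetect = audit2$removed)
  validate_cohort(out)
  list(cohort = out, audits = list(audit1, audit2))
}

#' @export
print.exclusion_audit <- function(x, ...) {
  cat(sprintf("Exclusion stage '%s': removed %d, remaining %d\n",
              x$stage, x$removed, x$remaining))
  invisible(x)
}

#' Write exclusion audits as a JSON report
#'
#' @param audits list of `exclusion_audit` objects from [apply_exclusions()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_audit <- function(audits, path) {
  payload <- lapply(audits, function(a) {
    list(stage = a$stage, removed = a$removed, remaining = a$remaining,
         reasons = a$reasons)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
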