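#' Urinary flow rate from void volume and time
#'
#' Single void: `UFR = V / t` (mL/min).  For pooled samples built from
#' several voids, the composite flow rate is the total volume over the total
#' time, `sum(V) / sum(t)`, so that laboratory measurements on the pooled
#' specimen correspond to the correct flow rate.
#'
#' @param volume void volume(s), mL.
#' @param time elapsed time(s) since previous void, min.
#' @param composite if `TRUE`, pool all (volume, time) pairs into one rate.
#' @return mL/min; vectorized unless `composite`.
#' @examples
#' ufr_from_void(105, 150)                     # 0.7
#' ufr_from_void(c(50, 70), c(60, 60), composite = TRUE)  # 1.0
#' @export
ufr_from_void <- function(volume, time, composite = FALSE) {
  if (any(time <= 0) || any(volume <= 0)) {
    stop("volume and time must be > 0", call. = FALSE)
  }
  if (composite) sum(volume) / sum(time) else volume / time
}

#' Analyte excretion rate
#'
#' `ER = C_vol * V / t` in ng/hr: the numeric ug/L value of the
#' concentration equals ng/mL, so multiplying by the void volume (mL) and
#' dividing by time (hours) gives ng/hr directly.  Equivalently
#' `ER = 60 * C_vol * UFR` with UFR in mL/min.
#'
#' @param c_vol concentration, ug/L (numerically ng/mL).
#' @param volume void volume, mL.
#' @param time elapsed time, hours.
#' @return ng/hr (vectorized).
#' @export
excretion_rate <- function(c_vol, volume, time) {
  if (any(c_vol <= 0) || any(volume <= 0) || any(time <= 0)) {
    stop("c_vol, volume and time must be > 0", call. = FALSE)
  }
  c_vol * volume / time
}

#' Bodyweight-normalised excretion rate
#'
#' `ERBW = C_vol * V / (t * BW)` in ng/kg-hr.
#'
#' @inheritParams excretion_rate
#' @param bodyweight kg.
#' @return ng/kg-hr (vectorized).
#' @export
excretion_rate_bw <- function(c_vol, volume, time, bodyweight) {
  if (any(bodyweight <= 0)) stop("bodyweight must be > 0", call. = FALSE)
  excretion_rate(c_vol, volume, time) / bodyweight
}

#' Creatinine adjustment
#'
#' `C / C_cr` expressed in ug/g creatinine (concentration in ug/L over
#' creatinine in g/L).  Assumes creatinine excretion is constant and varies
#' only with urinary flow.
#'
#' @param c_vol concentration, ug/L.
#' @param c_cr urinary creatinine, g/L, > 0.
#' @return ug/g creatinine (vectorized).
#' @export
creatinine_adjust <- function(c_vol, c_cr) {
  if (any(c_cr <= 0)) stop("creatinine must be > 0", call. = FALSE)
  c_vol / c_cr
}

#' Osmolality adjustment (Levine-Fahy form)
#'
#' `C * Osm_ref / Osm_meas`: scales the concentration to what it would be at
#' a reference osmolality, conventionally the training-split median.
#'
#' @param c_vol concentration, ug/L.
#' @param osm_meas specimen osmolality, mOsm/kg, > 0.
#' @param osm_ref reference osmolality, mOsm/kg, > 0.
#' @return ug/L at the reference osmolality (vectorized).
#' @export
osmolality_adjust <- function(c_vol, osm_meas, osm_ref) {
  if (any(osm_meas <= 0) || any(osm_ref <= 0)) {
    stop("osmolality values must be > 0", call. = FALSE)
  }
  c_vol * osm_ref / osm_meas
}

#' Flow-rate power-law (Araki) adjustment
#'
#' `C * UFR^b` standardises the concentration to a urinary flow rate of
#' 1 mL/min using an analyte-specific exponent `b`.  `b = 0` leaves the
#' concentration unchanged; `b = 1` is the exponent implicit in conventional
#' excretion-rate adjustment.
#'
#' @param c_vol concentration, ug/L.
#' @param ufr urinary flow rate, mL/min, > 0.
#' @param b dimensionless exponent, finite.
#' @return ug/L at UFR 1 mL/min (vectorized).
#' @export
ufr_power_adjust <- function(c_vol, ufr, b) {
  if (any(ufr <= 0)) stop("ufr must be > 0", call. = FALSE)
  if (any(!is.finite(b))) stop("b must be finite", call. = FALSE)
  c_vol * ufr^b
}

#' Inorganic arsenic and methylated metabolites (AsIMM)
#'
#' The sum of arsenous acid (As(III)), arsenic acid (As(V)),
#' monomethylarsonic acid (MMA) and dimethylarsonic acid (DMA) - the routine
#' arsenic exposure biomarker, excluding non-toxic arsenobetaine.  Species
#' below their detection limit are stored at the limit; the `policy`
#' controls how such values enter the sum: kept as-is (default), divided by
#' `sqrt(2)`, or zeroed.
#'
#' @param as3,as5,mma,dma species concentrations, ug/L (non-detects stored at
#'   the detection limit).
#' @param detect optional logical matrix/data frame with one column per
#'   species (same order) marking detected values; `NULL` treats everything
#'   as detected.
#' @param policy non-detect substitution policy.
#' @return ug/L (vectorized).
#' @examples
#' as_imm(1, 0.5, 1.5, 3)  # 6
#' @export
as_imm <- function(as3, as5, mma, dma, detect = NULL,
                   policy = c("as_is", "lod_sqrt2", "zero")) {
  policy <- match.arg(policy)
  sp <- cbind(as3, as5, mma, dma)
  if (any(sp < 0, na.rm = TRUE)) stop("species concentrations must be >= 0", call. = FALSE)
  if (any(rowSums(!is.na(sp)) == 0)) {
    stop("all four arsenic species missing for at least one record", call. = FALSE)
  }
  if (!is.null(detect) && policy != "as_is") {
    det <- as.matrix(detect)
    factor <- switch(policy, lod_sqrt2 = 1 / sqrt(2), zero = 0)
    sp[!det] <- sp[!det] * factor
  }
  rowSums(sp, na.rm = TRUE)
}

.adjust_methods <- c("unadjusted", "creatinine", "osmolality", "er", "erbw",
                     "ufr_power")

#' Adjust every record and analyte in a cohort by one method
#'
#' Applies the chosen hydration-adjustment transform to each record and each
#' requested analyte, returning a long table of per-volunteer adjusted
#' values with their units.  `method = "unadjusted"` passes the volume-based
#' concentrations through.
#'
#' @param x an eligible [cohort()].
#' @param method one of `"unadjusted"`, `"creatinine"`, `"osmolality"`,
#'   `"er"`, `"erbw"`, `"ufr_power"`.
#' @param analytes analyte keys understood by [analyte_values()].
#' @param b named vector of flow-rate exponents per analyte (required for
#'   `"ufr_power"`).
#' @param osm_ref reference osmolality in mOsm/kg, or `"auto"` to use the
#'   median osmolality of `x` (required for `"osmolality"`).
#' @param nondetect non-detect policy for the AsIMM composite.
#' @return data frame of class `"adjustment_result"` with columns `sqn`,
#'   `analyte`, `method`, `value`, `units`, and (where applicable) `b_used`,
#'   `osm_ref_used`.
#' @examples
#' ch <- generate_cohort(synthetic_params(n = 50, seed = 3))
#' head(adjust_cohort(ch, "creatinine", analytes = "pb"))
#' @export
adjust_cohort <- function(x, method = .adjust_methods,
                          analytes = c("pb", "cd", "as_imm", "i"),
                          b = NULL, osm_ref = NULL,
                          nondetect = c("as_is", "lod_sqrt2", "zero")) {
  stopifnot(inherits(x, "cohort"))
  method <- match.arg(method)
  nondetect <- match.arg(nondetect)
  rec <- x$records
  if (method == "osmolality") {
    if (is.null(osm_ref)) stop("osm_ref required for osmolality adjustment", call. = FALSE)
    if (identical(osm_ref, "auto")) osm_ref <- stats::median(rec$osmolality)
  }
  if (method == "erbw" && any(is.na(rec$bodyweight))) {
    stop("bodyweight missing; required for erbw", call. = FALSE)
  }
  out <- lapply(analytes, function(an) {
    cv <- analyte_values(x, an, nondetect = nondetect)
    res <- switch(method,
      unadjusted = list(value = cv, units = "ug/L"),
      creatinine = list(value = creatinine_adjust(cv, rec$urine_creatinine),
                        units = "ug/g creatinine"),
      osmolality = list(value = osmolality_adjust(cv, rec$osmolality, osm_ref),
                        units = sprintf("ug/L at %g mOsm/kg", osm_ref)),
      er = list(value = excretion_rate(cv, rec$void_volume,
                                       rec$void_time / 60),
                units = "ng/hr"),
      erbw = list(value = excretion_rate_bw(cv, rec$void_volume,
                                            rec$void_time / 60,
                                            rec$bodyweight),
                  units = "ng/kg-hr"),
      ufr_power = {
        if (is.null(b) || is.null(b[[an]]) || is.na(b[[an]])) {
          stop("no b value supplied for analyte ", an, call. = FALSE)
        }
        list(value = ufr_power_adjust(cv, rec$ufr, b[[an]]),
             units = "ug/L at UFR 1 mL/min")
      }
    )
    d <- data.frame(sqn = rec$sqn, analyte = an, method = method,
                    value = res$value, units = res$units,
                    stringsAsFactors = FALSE)
    if (method == "ufr_power") d$b_used <- b[[an]]
    if (method == "osmolality") d$osm_ref_used <- osm_ref
    d
  })
  res <- do.call(rbind, out)
  class(res) <- c("adjustment_result", "data.frame")
  res
}
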