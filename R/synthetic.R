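#' Parameters for the synthetic-cohort generator
#'
#' The generator emulates the statistical structure that hydration-adjustment
#' analyses assume: on the natural-log scale each urinary analyte follows the
#' dilution model `ln C = a + D - b * ln UFR + e`, where `UFR` is the urinary
#' flow rate (mL/min), `D` is a latent per-person internal dose
#' (`Normal(0, sigma_dose)`), `b` is the analyte-specific flow-rate exponent
#' and `e` is residual noise (`Normal(0, sigma_noise)`).  Blood
#' concentrations couple to the same latent dose (`blood_coupling` is the
#' correlation of ln blood with `D`), which is what makes flow-rate-based and
#' blood-based optimisation criteria distinguishable.  Creatinine and
#' osmolality are generated from their own dilution blocks, making them
#' imperfect flow-rate surrogates.  Exclusion covariates (albuminuria,
#' diabetes, chronic kidney disease) are generated marginally independent of
#' the dilution variables, each triggering its exclusion rule at the
#' configured rate.
#'
#' Default geometric-mean scales: creatinine 1.1 g/L, osmolality 635 mOsm/kg,
#' UFR 0.7 mL/min, urinary Pb 0.5 / Cd 0.2 / AsIMM 6.3 / I 149 ug/L, blood Pb
#' 1.1 ug/dL, blood Cd 0.3 ug/L.  Default exponents: Pb 0.38, Cd 0.32, AsIMM
#' 0.27, I 0.45, creatinine 0.52.  Intercepts `a` are derived from the target
#' geometric means as `a = ln(gm) + b_true * ufr_mu`.
#'
#' @param n number of volunteers (>= 2).
#' @param seed integer RNG seed; identical parameters give a byte-identical
#'   serialized cohort.
#' @param analytes named list of per-analyte blocks, each with `gm` (ug/L
#'   geometric-mean target), `b_true`, `sigma_dose`, `sigma_noise`,
#'   `blood_coupling`, `lod` (ug/L), and for blood-paired analytes
#'   `blood_gm`, `blood_sigma`.
#' @param ufr_mu,ufr_sigma mean and SD of ln UFR (UFR in mL/min).
#' @param creatinine,osmolality dilution blocks: `gm`, `b_true`, `sigma`.
#' @param demographics list with `gender_ethnicity` (6-cell named proportion
#'   table) and `age_bands` (5-band proportions with `lo`/`hi` limits in
#'   years).
#' @param exclusion_rates named rates in `[0,1)` for `albuminuria`,
#'   `diabetes`, `ckd`.
#' @param nondetect_rate if not `NULL`, overall probability that a record is
#'   non-detect for at least one of urinary Pb, Cd, total As, I; detection
#'   limits for those analytes are then placed at the matching per-analyte
#'   quantile of the generated concentrations instead of the fixed `lod`
#'   values.
#' @param species_fractions fixed proportions splitting AsIMM into
#'   As(III)/As(V)/MMA/DMA (must sum to 1).
#' @return A validated object of class `"synthetic_params"`.
#' @export
synthetic_params <- function(n = 2151,
                             seed = 1L,
                             analytes = default_analyte_params(),
                             ufr_mu = log(0.7),
                             ufr_sigma = 0.8,
                             creatinine = list(gm = 1.1, b_true = 0.52, sigma = 0.45),
                             osmolality = list(gm = 635, b_true = 0.45, sigma = 0.25),
                             demographics = default_demographics(),
                             exclusion_rates = c(albuminuria = 0.08,
                                                 diabetes = 0.10,
                                                 ckd = 0.08),
                             nondetect_rate = NULL,
                             species_fractions = c(as3 = 0.08, as5 = 0.03,
                                                   mma = 0.14, dma = 0.75)) {
  p <- structure(
    list(n = as.integer(n), seed = as.integer(seed), analytes = analytes,
         ufr_mu = ufr_mu, ufr_sigma = ufr_sigma,
         creatinine = creatinine, osmolality = osmolality,
         demographics = demographics, exclusion_rates = exclusion_rates,
         nondetect_rate = nondetect_rate,
         species_fractions = species_fractions),
    class = "synthetic_params"
  )
  validate_synthetic_params(p)
  p
}

#' Default per-analyte generator blocks
#'
#' Geometric-mean scales and flow-rate exponents match typical US
#' population-survey spot-urine values; dose and noise dispersions are chosen
#' so that the ln-scale spread of each analyte resembles the several-hundred-
#' fold concentration ranges seen in such surveys, with the latent internal
#' dose contributing more variance than residual noise.
#'
#' @return named list of analyte parameter blocks for [synthetic_params()].
#' @export
default_analyte_params <- function() {
  list(
    pb = list(gm = 0.5, b_true = 0.38, sigma_dose = 0.70, sigma_noise = 0.45,
              blood_coupling = 0.85, lod = 0.03,
              blood_gm = 1.1, blood_sigma = 0.65),
    cd = list(gm = 0.2, b_true = 0.32, sigma_dose = 0.75, sigma_noise = 0.50,
              blood_coupling = 0.80, lod = 0.02,
              blood_gm = 0.3, blood_sigma = 0.65),
    as_imm = list(gm = 6.3, b_true = 0.27, sigma_dose = 0.80,
                  sigma_noise = 0.55, blood_coupling = 0, lod = 0.6,
                  blood_gm = NA_real_, blood_sigma = NA_real_),
    i = list(gm = 149, b_true = 0.45, sigma_dose = 0.85, sigma_noise = 0.55,
             blood_coupling = 0, lod = 2.4,
             blood_gm = NA_real_, blood_sigma = NA_real_)
  )
}

#' Default demographic structure
#'
#' Gender-by-ethnicity and age-band proportions approximating a three-
#' ethnicity US survey design (non-Hispanic white 49%, non-Hispanic black
#' 28%, Mexican American 23%; male 51%), with five age bands 6-11, 12-19,
#' 20-39, 40-59 and over 60 years at 8/16/32/27/17%.
#'
#' @return list with `gender_ethnicity` and `age_bands` components.
#' @export
default_demographics <- function() {
  eth <- c(non_hispanic_white = 0.49, non_hispanic_black = 0.28,
           mexican_american = 0.23)
  gender <- c(male = 0.51, female = 0.49)
  ge <- as.vector(outer(gender, eth))
  names(ge) <- as.vector(outer(names(gender), names(eth), paste, sep = "."))
  list(
    gender_ethnicity = ge,
    age_bands = data.frame(
      band = c("6-11", "12-19", "20-39", "40-59", ">60"),
      lo = c(6, 12, 20, 40, 60),
      hi = c(11, 19, 39, 59, 80),
      prop = c(0.08, 0.16, 0.32, 0.27, 0.17),
      height_mean = c(135, 163, 170, 169, 167),
      height_sd = c(10, 9, 9, 9, 9),
      weight_mean = c(32, 60, 78, 82, 78),
      weight_sd = c(7, 12, 16, 17, 15)
    )
  )
}

#' @rdname synthetic_params
#' @param p a `synthetic_params` object.
#' @export
validate_synthetic_params <- function(p) {
  stopifnot(inherits(p, "synthetic_params"))
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  if (!num_ok(p$n) || p$n < 2) stop("n must be a finite count >= 2", call. = FALSE)
  if (!num_ok(c(p$ufr_mu, p$ufr_sigma)) || p$ufr_sigma < 0) {
    stop("ufr_mu/ufr_sigma must be finite with ufr_sigma >= 0", call. = FALSE)
  }
  for (nm in names(p$analytes)) {
    a <- p$analytes[[nm]]
    core <- c(a$gm, a$b_true, a$sigma_dose, a$sigma_noise, a$blood_coupling, a$lod)
    if (!num_ok(core)) stop("non-finite parameter in analyte block ", nm, call. = FALSE)
    if (a$b_true < 0) stop("b_true must be >= 0 (analyte ", nm, ")", call. = FALSE)
    if (a$sigma_dose < 0 || a$sigma_noise < 0) {
      stop("negative sigma in analyte block ", nm, call. = FALSE)
    }
    if (a$blood_coupling < 0 || a$blood_coupling > 1) {
      stop("blood_coupling must lie in [0, 1] (analyte ", nm, ")", call. = FALSE)
    }
  }
  for (blk in list(p$creatinine, p$osmolality)) {
    if (!num_ok(c(blk$gm, blk$b_true, blk$sigma)) || blk$sigma < 0 || blk$b_true < 0) {
      stop("invalid creatinine/osmolality block", call. = FALSE)
    }
  }
  ge <- p$demographics$gender_ethnicity
  if (any(ge < 0) || abs(sum(ge) - 1) > 1e-9) {
    stop("gender_ethnicity proportions must be >= 0 and sum to 1", call. = FALSE)
  }
  ab <- p$demographics$age_bands
  if (any(ab$prop < 0) || abs(sum(ab$prop) - 1) > 1e-9) {
    stop("age_band proportions must be >= 0 and sum to 1", call. = FALSE)
  }
  if (any(p$exclusion_rates < 0) || any(p$exclusion_rates >= 1)) {
    stop("exclusion rates must lie in [0, 1)", call. = FALSE)
  }
  if (abs(sum(p$species_fractions) - 1) > 1e-9) {
    stop("species_fractions must sum to 1", call. = FALSE)
  }
  invisible(p)
}

## truncated-at-lower-bound normal draw (simple resample; bounds are mild)
.rnorm_pos <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

#' Generate a synthetic cohort
#'
#' Draws `params$n` volunteer records from the generative model described in
#' [synthetic_params()].  For each volunteer: `ln UFR ~ Normal(ufr_mu,
#' ufr_sigma)`; per analyte a latent dose `D ~ Normal(0, sigma_dose)` and
#' `ln C = a + D - b_true * ln UFR + Normal(0, sigma_noise)`; blood
#' concentrations are `blood_coupling` correlated with the standardized
#' latent dose and scaled to the blood geometric mean; creatinine and
#' osmolality come from their own dilution blocks; demographics follow the
#' configured proportions; exclusion covariates are constructed so that each
#' eligibility rule fires at its configured rate; concentrations below the
#' detection limit are replaced by the limit and flagged non-detect.
#'
#' @param params a [synthetic_params()] object.
#' @return a [cohort()] whose provenance records the source `"synthetic"` and
#'   the seed.  Identical `params` yield identical cohorts.
#' @examples
#' ch <- generate_cohort(synthetic_params(n = 200, seed = 42))
#' exp(mean(log(ch$records$ufr)))   # geometric-mean UFR near 0.7 mL/min
#' @export
generate_cohort <- function(params) {
  validate_synthetic_params(params)
  n <- params$n
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(params$seed)

  ## demographics -----------------------------------------------------------
  ge <- params$demographics$gender_ethnicity
  cell <- sample(names(ge), n, replace = TRUE, prob = ge)
  gender <- sub("\\..*$", "", cell)
  ethnicity <- sub("^[^.]*\\.", "", cell)
  ab <- params$demographics$age_bands
  band_idx <- sample(seq_len(nrow(ab)), n, replace = TRUE, prob = ab$prop)
  age <- stats::runif(n, ab$lo[band_idx], ab$hi[band_idx] + 1)  # continuous years
  age <- pmin(age, ab$hi[band_idx] + 0.999)
  height <- .rnorm_pos(n, ab$height_mean[band_idx], ab$height_sd[band_idx], 80)
  bodyweight <- .rnorm_pos(n, ab$weight_mean[band_idx], ab$weight_sd[band_idx], 12)

  ## dilution ---------------------------------------------------------------
  ln_ufr <- stats::rnorm(n, params$ufr_mu, params$ufr_sigma)
  ufr <- exp(ln_ufr)
  void_time <- stats::runif(n, 60, 240)            # min since previous void
  void_volume <- ufr * void_time                   # mL; keeps UFR = V/t exact

  cr <- params$creatinine
  urine_creatinine <- exp(log(cr$gm) + cr$b_true * params$ufr_mu -
                            cr$b_true * ln_ufr + stats::rnorm(n, 0, cr$sigma))
  os <- params$osmolality
  osmolality <- exp(log(os$gm) + os$b_true * params$ufr_mu -
                      os$b_true * ln_ufr + stats::rnorm(n, 0, os$sigma))

  ## analytes ---------------------------------------------------------------
  conc <- list(); blood <- list()
  for (nm in names(params$analytes)) {
    a <- params$analytes[[nm]]
    a_int <- log(a$gm) + a$b_true * params$ufr_mu      # ln ug/L at UFR = 1
    dose <- stats::rnorm(n, 0, a$sigma_dose)
    ln_c <- a_int + dose - a$b_true * ln_ufr + stats::rnorm(n, 0, a$sigma_noise)
    conc[[nm]] <- exp(ln_c)
    if (!is.na(a$blood_gm)) {
      z <- if (a$sigma_dose > 0) dose / a$sigma_dose else stats::rnorm(n)
      ln_b <- log(a$blood_gm) + a$blood_sigma *
        (a$blood_coupling * z +
           sqrt(max(0, 1 - a$blood_coupling^2)) * stats::rnorm(n))
      blood[[nm]] <- exp(ln_b)
    }
  }
  sf <- params$species_fractions
  urine_as3 <- sf[["as3"]] * conc$as_imm
  urine_as5 <- sf[["as5"]] * conc$as_imm
  urine_mma <- sf[["mma"]] * conc$as_imm
  urine_dma <- sf[["dma"]] * conc$as_imm
  arsenobetaine <- exp(stats::rnorm(n, log(1.5), 1.0))
  urine_total_as <- conc$as_imm + arsenobetaine

  ## exclusion covariates ---------------------------------------------------
  rates <- params$exclusion_rates
  alb_hit <- stats::runif(n) < rates[["albuminuria"]]
  acr <- ifelse(alb_hit, 30 * (1.1 + stats::rexp(n)), stats::runif(n, 2, 25))
  urinary_albumin <- acr * urine_creatinine          # mg/L = (mg/g) * (g/L)

  dia_hit <- stats::runif(n) < rates[["diabetes"]]
  dia_self <- dia_hit & stats::runif(n) < 0.5
  selfreport_diabetes <- dia_self
  plasma_glucose <- stats::runif(n, 80, 110)
  fasting_hours <- stats::runif(n, 2, 14)
  lab_dia <- dia_hit & !dia_self
  plasma_glucose[lab_dia] <- stats::runif(sum(lab_dia), 210, 300)
  fasting_hours[lab_dia] <- stats::runif(sum(lab_dia), 2, 14)

  ckd_hit <- stats::runif(n) < rates[["ckd"]]
  ckd_self <- ckd_hit & stats::runif(n) < 0.5
  selfreport_ckd <- ckd_self
  adult <- age >= 18
  ## eGFR-driven serum creatinine: healthy adults 0.6-0.85 mg/dL keeps
  ## CKD-EPI >= 60 across ages <= 81; children are assigned a target eGFR
  serum_creatinine <- ifelse(adult, stats::runif(n, 0.60, 0.85),
                             0.413 * height / stats::runif(n, 75, 130))
  lab_ckd <- ckd_hit & !ckd_self
  serum_creatinine[lab_ckd & adult] <- stats::runif(sum(lab_ckd & adult), 2.8, 4.0)
  kid_ckd <- lab_ckd & !adult
  serum_creatinine[kid_ckd] <- 0.413 * height[kid_ckd] /
    stats::runif(sum(kid_ckd), 30, 50)

  ## detection limits -------------------------------------------------------
  lods <- vapply(params$analytes, `[[`, numeric(1), "lod")
  lod_total_as <- 0.3
  if (!is.null(params$nondetect_rate)) {
    q <- 1 - (1 - params$nondetect_rate)^(1 / 4)   # per-analyte share of the union
    lods[["pb"]] <- stats::quantile(conc$pb, q, names = FALSE)
    lods[["cd"]] <- stats::quantile(conc$cd, q, names = FALSE)
    lods[["i"]] <- stats::quantile(conc$i, q, names = FALSE)
    lod_total_as <- stats::quantile(urine_total_as, q, names = FALSE)
  }
  censor <- function(x, lod) {
    det <- x >= lod
    list(value = ifelse(det, x, lod), detect = det)
  }
  c_pb <- censor(conc$pb, lods[["pb"]])
  c_cd <- censor(conc$cd, lods[["cd"]])
  c_i <- censor(conc$i, lods[["i"]])
  sp_lod <- lods[["as_imm"]] * sf                    # per-species limits
  c_as3 <- censor(urine_as3, sp_lod[["as3"]])
  c_as5 <- censor(urine_as5, sp_lod[["as5"]])
  c_mma <- censor(urine_mma, sp_lod[["mma"]])
  c_dma <- censor(urine_dma, sp_lod[["dma"]])
  c_tas <- censor(urine_total_as, lod_total_as)

  rec <- data.frame(
    sqn = seq_len(n),
    gender = gender, ethnicity = ethnicity, age = age,
    bodyweight = bodyweight, height = height,
    void_volume = void_volume, void_time = void_time, ufr = ufr,
    urine_creatinine = urine_creatinine, osmolality = osmolality,
    urine_pb = c_pb$value, urine_cd = c_cd$value, urine_i = c_i$value,
    urine_as3 = c_as3$value, urine_as5 = c_as5$value,
    urine_mma = c_mma$value, urine_dma = c_dma$value,
    urine_total_as = c_tas$value,
    blood_pb = blood$pb, blood_cd = blood$cd,
    urinary_albumin = urinary_albumin,
    serum_creatinine = serum_creatinine,
    plasma_glucose = plasma_glucose, fasting_hours = fasting_hours,
    selfreport_diabetes = selfreport_diabetes,
    selfreport_ckd = selfreport_ckd,
    detect_pb = c_pb$detect, detect_cd = c_cd$detect, detect_i = c_i$detect,
    detect_as3 = c_as3$detect, detect_as5 = c_as5$detect,
    detect_mma = c_mma$detect, detect_dma = c_dma$detect,
    detect_total_as = c_tas$detect,
    stringsAsFactors = FALSE
  )
  cohort(rec, provenance = list(source = "synthetic", seed = params$seed,
                                initial_n = n))
}
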