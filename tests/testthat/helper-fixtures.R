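# Hand-built cohort fixture: n benign volunteers (no exclusion triggers, all
# analytes detected).  Individual rows are perturbed inside tests.
make_test_records <- function(n = 5, ufr = rep(1, n)) {
  void_time <- rep(120, n)
  data.frame(
    sqn = seq_len(n),
    gender = rep(c("male", "female"), length.out = n),
    ethnicity = rep("non_hispanic_white", n),
    age = rep(30, n),
    bodyweight = rep(70, n),
    height = rep(170, n),
    void_volume = ufr * void_time,
    void_time = void_time,
    ufr = ufr,
    urine_creatinine = rep(1.1, n),
    osmolality = rep(600, n),
    urine_pb = seq(0.3, 0.8, length.out = n),
    urine_cd = seq(0.1, 0.3, length.out = n),
    urine_i = seq(100, 200, length.out = n),
    urine_as3 = rep(0.5, n),
    urine_as5 = rep(0.2, n),
    urine_mma = rep(0.9, n),
    urine_dma = rep(4.5, n),
    urine_total_as = rep(7.5, n),
    blood_pb = seq(0.8, 1.5, length.out = n),
    blood_cd = seq(0.2, 0.5, length.out = n),
    urinary_albumin = rep(11, n),       # ACR 10 mg/g at creatinine 1.1 g/L
    serum_creatinine = rep(0.8, n),
    plasma_glucose = rep(90, n),
    fasting_hours = rep(10, n),
    selfreport_diabetes = rep(FALSE, n),
    selfreport_ckd = rep(FALSE, n),
    detect_pb = rep(TRUE, n),
    detect_cd = rep(TRUE, n),
    detect_i = rep(TRUE, n),
    detect_as3 = rep(TRUE, n),
    detect_as5 = rep(TRUE, n),
    detect_mma = rep(TRUE, n),
    detect_dma = rep(TRUE, n),
    detect_total_as = rep(TRUE, n),
    stringsAsFactors = FALSE
  )
}

make_test_cohort <- function(n = 5, ufr = rep(1, n), ...) {
  rec <- make_test_records(n, ufr)
  extra <- list(...)
  for (nm in names(extra)) rec[[nm]] <- extra[[nm]]
  cohort(rec, provenance = list(source = "fixture", seed = NA_integer_))
}

# Noise-free synthetic parameters: concentrations are deterministic
# functions of UFR, so regression slopes recover the exponents exactly.
noiseless_params <- function(n = 100, seed = 1) {
  an <- default_analyte_params()
  for (nm in names(an)) {
    an[[nm]]$sigma_dose <- 0
    an[[nm]]$sigma_noise <- 0
  }
  synthetic_params(n = n, seed = seed, analytes = an)
}
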