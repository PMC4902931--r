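test_that("noise-free dilution is inverted exactly, with the cancellation convention", {
  set.seed(1)
  ln_u <- rnorm(50)
  fit <- profile_b(-0.4 * ln_u, ln_u, criterion = "A")
  expect_equal(fit$b_opt, 0.40)
  expect_equal(fit$r_opt, 0)        # adjusted series exactly constant
})

test_that("exact zero sample covariance puts the optimum at b = 0", {
  set.seed(2)
  ln_u <- rnorm(60)
  ln_c <- residuals(lm(rnorm(60) ~ ln_u))   # orthogonal to ln_u by construction
  fit <- profile_b(as.numeric(ln_c), ln_u, criterion = "A")
  expect_equal(fit$b_opt, 0.00)
})

test_that("the closed form recovers exact slopes and flags degenerate input", {
  set.seed(3)
  ln_u <- rnorm(30)
  expect_equal(closed_form_b(3 - 0.52 * ln_u, ln_u), 0.52, tolerance = 1e-12)
  expect_equal(closed_form_b(rep(2, 30), ln_u), 0)
  expect_error(closed_form_b(rnorm(5), rep(1, 5)), "zero variance")
})

test_that("grid optimum sits within half a step of the closed form", {
  set.seed(4)
  for (i in 1:25) {
    n <- sample(c(50, 200, 500), 1)
    ln_u <- rnorm(n, 0, runif(1, 0.5, 1.2))
    b0 <- runif(1, 0, 1.5)
    ln_c <- 1 - b0 * ln_u + rnorm(n, 0, runif(1, 0.2, 1))
    cf <- closed_form_b(ln_c, ln_u)
    fit <- profile_b(ln_c, ln_u, criterion = "A")
    if (cf >= 0 && cf <= 1.5) {
      expect_lte(abs(fit$b_opt - cf), 0.005 + 1e-12)
    }
  }
})

test_that("roots outside the grid clip to its endpoints", {
  set.seed(5)
  ln_u <- rnorm(80)
  steep <- 1 - 2.0 * ln_u + rnorm(80, 0, 0.1)    # root near 2.0
  expect_equal(profile_b(steep, ln_u)$b_opt, 1.5)
  rising <- 1 + 0.5 * ln_u + rnorm(80, 0, 0.1)   # root near -0.5
  expect_equal(profile_b(rising, ln_u)$b_opt, 0)
})

test_that("criterion A correlation is non-decreasing in b", {
  set.seed(6)
  for (i in 1:20) {
    n <- 50 + i
    ln_u <- rnorm(n)
    ln_c <- rnorm(n, 0, runif(1, 0.3, 2)) - runif(1, 0, 1) * ln_u
    fit <- profile_b(ln_c, ln_u, criterion = "A")
    expect_true(all(diff(fit$r) >= -1e-12))
    if (abs(cor(ln_c, ln_u)) < 1) expect_true(all(diff(fit$r) > 0))
  }
})

test_that("criterion B maximises the signed correlation with blood", {
  ch <- generate_cohort(synthetic_params(n = 800, seed = 7))
  fit <- araki_b(ch, "pb", criterion = "B")
  expect_gte(fit$r_opt, max(fit$r) - 1e-15)
  expect_equal(fit$b_opt, fit$grid[which.max(fit$r)])
  expect_error(profile_b(rnorm(10), rnorm(10), criterion = "B"), "target")
})

test_that("input degeneracies and short vectors are rejected", {
  expect_error(profile_b(rnorm(3), rnorm(3)), "at least 4")
  expect_error(profile_b(rnorm(10), rep(1, 10)), "zero variance")
  expect_error(profile_b(c(rnorm(9), NA), rnorm(10)), "non-finite")
})

test_that("fitting on a testing split is refused unless overridden", {
  ch <- generate_cohort(synthetic_params(n = 60, seed = 8))
  sp <- split_cohort(ch, seed = 1)
  halves <- apply_split(ch, sp)
  expect_error(araki_b(halves$testing, "pb"), "testing split")
  expect_s3_class(araki_b(halves$testing, "pb", allow_testing = TRUE),
                  "b_profile")
  expect_s3_class(araki_b(halves$training, "pb"), "b_profile")
})

test_that("undersized subgroups are skipped with a warning", {
  rec <- make_test_records(5, ufr = c(0.5, 0.8, 1, 1.3, 2))
  rec$age <- c(8, 15, 30, 50, 70)     # one record in each band
  ch <- cohort(rec, provenance = list(source = "fixture", seed = NA))
  w <- capture_warnings(bt <- derive_b(ch, analytes = "pb", grouping = "age_band"))
  expect_length(w, 5L)                      # one warning per skipped band
  expect_true(all(grepl("skipped", w)))
  expect_equal(nrow(bt), 0L)
})

test_that("subgroup estimates tighten around a homogeneous exponent as n grows", {
  spread_at <- function(n) {
    ch <- generate_cohort(synthetic_params(n = n, seed = 21))
    bt <- derive_b(ch, analytes = "pb", grouping = "age_band")
    max(bt$b_opt) - min(bt$b_opt)
  }
  expect_lt(spread_at(8000), spread_at(400))
})

test_that("age-varying exponents are recovered in rank order", {
  # build a cohort whose exponent rises with age band
  set.seed(22)
  n_band <- 600
  bands <- data.frame(age = c(8, 15, 30, 50, 70), b = c(0.1, 0.2, 0.3, 0.4, 0.5))
  recs <- lapply(seq_len(nrow(bands)), function(i) {
    ln_u <- rnorm(n_band, log(0.7), 0.8)
    rec <- make_test_records(n_band, ufr = exp(ln_u))
    rec$age <- bands$age[i]
    rec$urine_pb <- exp(log(0.5) - bands$b[i] * ln_u + rnorm(n_band, 0, 0.5))
    rec$sqn <- rec$sqn + (i - 1) * n_band
    rec
  })
  ch <- cohort(do.call(rbind, recs),
               provenance = list(source = "fixture", seed = 22))
  bt <- derive_b(ch, analytes = "pb", grouping = "age_band")
  bt <- bt[match(c("6-11", "12-19", "20-39", "40-59", ">60"), bt$subgroup), ]
  expect_false(is.unsorted(bt$b_opt))
})

test_that("applying exponents dispatches per record and validates coverage", {
  ch <- generate_cohort(synthetic_params(n = 40, seed = 23))
  bt0 <- data.frame(analyte = "pb", subgroup = "all", criterion = "A",
                    b_opt = 0, r_opt = NA, n = 40, slope_p = NA)
  out <- apply_b(ch, bt0, mode = "global")
  expect_equal(out$value, analyte_values(ch, "pb"))

  # identical per-subgroup exponents reproduce the global adjustment
  bt_sub <- data.frame(analyte = "pb",
                       subgroup = c("6-11", "12-19", "20-39", "40-59", ">60"),
                       criterion = "A", b_opt = 0.35, r_opt = NA, n = 8,
                       slope_p = NA)
  bt_glob <- transform(bt0, b_opt = 0.35)
  out_sub <- apply_b(ch, bt_sub, mode = "per_subgroup", grouping = "age_band")
  out_glob <- apply_b(ch, bt_glob, mode = "global")
  expect_equal(out_sub$value, out_glob$value)

  expect_error(apply_b(ch, bt_sub[-3, ], mode = "per_subgroup",
                       grouping = "age_band"), "no b value for subgroup")
})

test_that("band-specific exponents give no material criterion-B gain under homogeneity", {
  ch <- generate_cohort(synthetic_params(n = 4000, seed = 24))
  bt_glob <- derive_b(ch, analytes = "pb", criterion = "B")
  bt_band <- derive_b(ch, analytes = "pb", criterion = "B",
                      grouping = "age_band")
  adj_glob <- apply_b(ch, bt_glob, mode = "global")
  adj_band <- apply_b(ch, bt_band, mode = "per_subgroup", grouping = "age_band")
  r_glob <- cor(log(adj_glob$value), log(ch$records$blood_pb))
  r_band <- cor(log(adj_band$value), log(ch$records$blood_pb))
  expect_lt(abs(r_glob - r_band), 0.05)
})
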