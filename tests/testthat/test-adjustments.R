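test_that("urinary flow rate handles single and composite voids", {
  expect_equal(ufr_from_void(120, 120), 1.0)
  expect_equal(ufr_from_void(c(50, 70), c(60, 60), composite = TRUE), 1.0)
  expect_equal(ufr_from_void(105, 150), 0.7)
  expect_error(ufr_from_void(100, 0), "> 0")
})

test_that("excretion rate and its bodyweight form agree with direct arithmetic", {
  expect_equal(excretion_rate(10, 120, 2), 600)
  expect_equal(excretion_rate(1, 1, 1), 1)
  expect_equal(excretion_rate_bw(10, 120, 2, 60), 10)
  set.seed(4)
  c_vol <- runif(50, 0.1, 50); vol <- runif(50, 20, 400)
  t_min <- runif(50, 30, 300); bw <- runif(50, 20, 120)
  # unit consistency: ER(ng/hr) = 60 * C(ng/mL) * UFR(mL/min)
  expect_equal(excretion_rate(c_vol, vol, t_min / 60),
               60 * c_vol * ufr_from_void(vol, t_min), tolerance = 1e-12)
  expect_equal(excretion_rate_bw(c_vol, vol, t_min / 60, bw),
               excretion_rate(c_vol, vol, t_min / 60) / bw, tolerance = 1e-12)
  expect_equal(excretion_rate_bw(c_vol, vol, t_min / 60, 1),
               excretion_rate(c_vol, vol, t_min / 60))
})

test_that("creatinine adjustment divides and factorises geometric means", {
  expect_equal(creatinine_adjust(0.5, 1.0), 0.5)
  expect_equal(creatinine_adjust(0.5, 0.5), 1.0)
  expect_error(creatinine_adjust(0.5, 0), "> 0")
  set.seed(5)
  cv <- rlnorm(40); cc <- rlnorm(40)
  expect_equal(geometric_mean(creatinine_adjust(cv, cc)),
               geometric_mean(cv) / geometric_mean(cc), tolerance = 1e-12)
})

test_that("osmolality adjustment scales to the reference", {
  expect_equal(osmolality_adjust(0.7, 500, 500), 0.7)
  expect_equal(osmolality_adjust(0.5, 367, 734), 1.0)
  expect_error(osmolality_adjust(0.5, 0, 734), "> 0")
})

test_that("flow-rate power adjustment has its algebraic identities", {
  expect_equal(ufr_power_adjust(3.2, 2.5, 0), 3.2)
  expect_equal(ufr_power_adjust(3.2, 1, 0.9), 3.2)
  expect_equal(ufr_power_adjust(5, 2, 1), 10)
  expect_error(ufr_power_adjust(1, -1, 0.5), "> 0")
  expect_error(ufr_power_adjust(1, 1, Inf), "finite")
})

test_that("the arsenic composite sums the four species under the chosen policy", {
  expect_equal(as_imm(1, 0.5, 1.5, 3), 6.0)
  # every species at its limit, as-is policy: the sum of the limits
  lods <- c(0.1, 0.05, 0.2, 0.3)
  expect_equal(as_imm(lods[1], lods[2], lods[3], lods[4],
                      detect = matrix(FALSE, 1, 4), policy = "as_is"),
               sum(lods))
  # one non-detect at limit 0.2 under the 1/sqrt(2) substitution
  expect_equal(as_imm(1, 0.2, 1, 1, detect = matrix(c(TRUE, FALSE, TRUE, TRUE), 1),
                      policy = "lod_sqrt2"),
               3 + 0.2 / sqrt(2))
  expect_equal(as_imm(1, 0.2, 1, 1, detect = matrix(c(TRUE, FALSE, TRUE, TRUE), 1),
                      policy = "zero"), 3)
  expect_error(as_imm(NA, NA, NA, NA), "missing")
})

test_that("cohort adjustment passes unadjusted values through and is deterministic", {
  ch <- make_test_cohort(3)
  out <- adjust_cohort(ch, "unadjusted", analytes = "pb")
  expect_equal(out$value, ch$records$urine_pb)
  expect_equal(out$units, rep("ug/L", 3))
  expect_identical(out, adjust_cohort(ch, "unadjusted", analytes = "pb"))
})

test_that("auto reference osmolality is the cohort median and GMs factorise", {
  ch <- generate_cohort(synthetic_params(n = 101, seed = 6))
  out <- adjust_cohort(ch, "osmolality", analytes = "cd", osm_ref = "auto")
  osm_ref <- median(ch$records$osmolality)
  expect_equal(out$osm_ref_used[1], osm_ref)
  expect_equal(geometric_mean(out$value),
               geometric_mean(ch$records$urine_cd) * osm_ref /
                 geometric_mean(ch$records$osmolality),
               tolerance = 1e-12)
})

test_that("excretion-rate units inflate the geometric mean far above ug/L", {
  ch <- generate_cohort(synthetic_params(n = 200, seed = 8))
  gm_unadj <- geometric_mean(adjust_cohort(ch, "unadjusted", analytes = "as_imm")$value)
  gm_er <- geometric_mean(adjust_cohort(ch, "er", analytes = "as_imm")$value)
  expect_gt(gm_er, 5 * gm_unadj)
})

test_that("every method is equivariant under rescaling of the input analyte", {
  ch <- generate_cohort(synthetic_params(n = 50, seed = 9))
  k <- 3.7
  ch_k <- ch
  ch_k$records$urine_pb <- k * ch$records$urine_pb
  for (m in c("unadjusted", "creatinine", "osmolality", "er", "erbw")) {
    a1 <- adjust_cohort(ch, m, analytes = "pb", osm_ref = 700)
    a2 <- adjust_cohort(ch_k, m, analytes = "pb", osm_ref = 700)
    expect_equal(a2$value, k * a1$value, tolerance = 1e-12)
  }
  a1 <- adjust_cohort(ch, "ufr_power", analytes = "pb", b = c(pb = 0.4))
  a2 <- adjust_cohort(ch_k, "ufr_power", analytes = "pb", b = c(pb = 0.4))
  expect_equal(a2$value, k * a1$value, tolerance = 1e-12)
})

test_that("adjustment commutes with subsetting records", {
  ch <- generate_cohort(synthetic_params(n = 40, seed = 10))
  keep <- ch$records$sqn[seq(1, 40, by = 2)]
  sub <- ch
  sub$records <- ch$records[match(keep, ch$records$sqn), ]
  sub$provenance$initial_n <- length(keep)
  whole <- adjust_cohort(ch, "creatinine", analytes = "i")
  part <- adjust_cohort(sub, "creatinine", analytes = "i")
  expect_equal(part$value, whole$value[match(keep, whole$sqn)])
})

test_that("method-specific requirements are enforced", {
  ch <- make_test_cohort(3)
  expect_error(adjust_cohort(ch, "ufr_power", analytes = "pb"), "no b value")
  expect_error(adjust_cohort(ch, "osmolality", analytes = "pb"), "osm_ref")
  ch$records$bodyweight[2] <- NA
  expect_error(adjust_cohort(ch, "erbw", analytes = "pb"), "bodyweight")
})
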