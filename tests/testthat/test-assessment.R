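test_that("the split has the documented sizes and is seed-deterministic", {
  ch <- generate_cohort(synthetic_params(n = 10, seed = 1))
  sp <- split_cohort(ch, fraction = 0.8, seed = 3)
  expect_length(sp$training_sqns, 8L)
  expect_length(sp$testing_sqns, 2L)
  expect_identical(sp, split_cohort(ch, fraction = 0.8, seed = 3))

  big <- generate_cohort(synthetic_params(n = 2151, seed = 1))
  sp2 <- split_cohort(big, fraction = 0.8, seed = 3)
  expect_length(sp2$training_sqns, 1721L)   # round(0.8 * 2151)
  expect_length(sp2$testing_sqns, 430L)
  expect_length(intersect(sp2$training_sqns, sp2$testing_sqns), 0L)
  expect_setequal(c(sp2$training_sqns, sp2$testing_sqns), big$records$sqn)

  expect_error(split_cohort(ch, fraction = 1.2), "fraction")
})

test_that("geometric mean obeys its log-arithmetic identities", {
  expect_equal(geometric_mean(c(1, 10, 100)), 10)
  expect_equal(geometric_mean(rep(3.7, 12)), 3.7)
  set.seed(2)
  x <- rlnorm(50)
  expect_equal(geometric_mean(5 * x), 5 * geometric_mean(x), tolerance = 1e-12)
  expect_error(geometric_mean(c(1, 0, 2)), "positive")
})

test_that("ln-scale Pearson matches cor.test on logged data", {
  set.seed(3)
  x <- rlnorm(60); y <- x^0.6 * rlnorm(60, 0, 0.4)
  mine <- ln_pearson(x, y)
  ref <- cor.test(log(x), log(y))
  expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  # interval uses the 1.96 quantile; cor.test uses qnorm(0.975)
  expect_equal(mine$ci_low, ref$conf.int[1], tolerance = 1e-4)
  expect_equal(mine$ci_high, ref$conf.int[2], tolerance = 1e-4)
})

test_that("perfectly dependent series give degenerate correlations", {
  x <- rlnorm(20)
  up <- ln_pearson(x, x)
  expect_equal(up$r, 1)
  expect_true(up$degenerate)
  down <- ln_pearson(x, 1 / x)
  expect_equal(down$r, -1)
  expect_error(ln_pearson(x, rep(2, 20)), "zero variance")
  expect_error(ln_pearson(c(-1, 1, 2, 3), 1:4), "> 0")
})

test_that("Fisher-z intervals achieve near-nominal coverage", {
  set.seed(4)
  rho <- 0.5; n <- 428
  hits <- vapply(1:500, function(i) {
    z <- matrix(rnorm(2 * n), n)
    x <- exp(z[, 1])
    y <- exp(rho * z[, 1] + sqrt(1 - rho^2) * z[, 2])
    ci <- ln_pearson(x, y)
    ci$ci_low <= rho && rho <= ci$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.925)
  expect_lte(mean(hits), 0.975)
})

test_that("Williams's statistic is zero at equality and antisymmetric", {
  w0 <- williams_test(0.5, 0.5, 0.3, 428)
  expect_equal(unname(w0$statistic), 0)
  expect_equal(w0$p.value, 1)
  a <- williams_test(0.8, 0.6, 0.5, 100)
  b <- williams_test(0.6, 0.8, 0.5, 100)
  expect_equal(unname(a$statistic), -unname(b$statistic), tolerance = 1e-12)
  expect_equal(unname(a$parameter), 97)
  expect_error(williams_test(0.9, -0.9, 0.9, 50), "positive semidefinite")
  expect_error(williams_test(0.5, 0.4, 0.3, 3), "at least 4")
  expect_error(williams_test(1, 0.4, 0.3, 30), "strictly inside")
})

test_that("compact letters express the significance pattern", {
  nm <- c("m1", "m2", "m3")
  none <- matrix(FALSE, 3, 3, dimnames = list(nm, nm))
  expect_equal(unname(compact_letters(none)), c("a", "a", "a"))

  all_sig <- matrix(TRUE, 3, 3, dimnames = list(nm, nm)); diag(all_sig) <- FALSE
  expect_equal(sort(unname(compact_letters(all_sig))), c("a", "b", "c"))

  # chain: 1~2, 2~3 but 1 and 3 differ
  chain <- none; chain["m1", "m3"] <- chain["m3", "m1"] <- TRUE
  expect_equal(compact_letters(chain),
               c(m1 = "a", m2 = "ab", m3 = "b"))
})

test_that("letter groups never merge significant nor separate non-significant pairs", {
  set.seed(5)
  for (k in 2:6) {
    for (rep in 1:10) {
      nm <- paste0("m", seq_len(k))
      sig <- matrix(FALSE, k, k, dimnames = list(nm, nm))
      pattern <- runif(k * (k - 1) / 2) < 0.4
      sig[upper.tri(sig)] <- pattern
      sig[lower.tri(sig)] <- t(sig)[lower.tri(sig)]
      lt <- compact_letters(sig)
      share <- function(a, b) {
        length(intersect(strsplit(lt[[a]], "")[[1]],
                         strsplit(lt[[b]], "")[[1]])) > 0
      }
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        expect_identical(share(nm[i], nm[j]), !sig[i, j])
      }
    }
  }
})

test_that("method assessment reproduces identities and refuses leaked exponents", {
  ch <- generate_cohort(synthetic_params(n = 500, seed = 6))
  sp <- split_cohort(ch, seed = 1)
  halves <- apply_split(ch, sp)
  bt <- rbind(derive_b(halves$training),
              derive_b(halves$training, analytes = c("pb", "cd"),
                       criterion = "B"))
  attr(bt, "split") <- "training"
  osm_ref <- median(halves$training$records$osmolality)
  res <- evaluate_methods(halves$testing, bt, osm_ref)

  # a zero exponent reproduces the unadjusted correlation bit for bit
  bt0 <- bt
  bt0$b_opt[bt0$analyte == "pb" & bt0$criterion == "A"] <- 0
  res0 <- evaluate_methods(halves$testing, bt0, osm_ref, analytes = "pb")
  rA <- function(d, m) d$r[d$criterion == "A" & d$method == m & d$analyte == "pb"]
  expect_identical(rA(res0, "ufra"), rA(res0, "unadjusted"))

  # creatinine criterion A equals the correlation of the log ratio directly
  r_direct <- cor(log(halves$testing$records$urine_pb /
                        halves$testing$records$urine_creatinine),
                  log(halves$testing$records$ufr))
  expect_equal(rA(res, "creatinine"), r_direct, tolerance = 1e-12)

  # leakage guard
  bt_bad <- bt
  attr(bt_bad, "split") <- "testing"
  expect_error(evaluate_methods(halves$testing, bt_bad, osm_ref), "leakage")
})

test_that("criterion-A method ranking is invariant to unit rescaling", {
  ch <- generate_cohort(synthetic_params(n = 400, seed = 7))
  sp <- split_cohort(ch, seed = 2)
  halves <- apply_split(ch, sp)
  bt <- derive_b(halves$training, analytes = "pb")
  osm_ref <- median(halves$training$records$osmolality)
  r1 <- evaluate_methods(halves$testing, bt, osm_ref, analytes = "pb",
                         blood_analytes = character(0))
  scaled <- halves$testing
  scaled$records$urine_pb <- 1000 * scaled$records$urine_pb   # ug/L -> ng/L
  r2 <- evaluate_methods(scaled, bt, osm_ref, analytes = "pb",
                         blood_analytes = character(0))
  expect_equal(r2$rank[order(r2$method)], r1$rank[order(r1$method)])
})

test_that("deriving on training and evaluating on testing leaves residual correlation", {
  ch <- generate_cohort(synthetic_params(n = 2151, seed = 8))
  sp <- split_cohort(ch, seed = 3)
  halves <- apply_split(ch, sp)
  fit <- araki_b(halves$training, "pb")
  # on its own training data the optimised exponent nulls the correlation
  expect_lte(abs(fit$r_opt), 0.01)
  # on the held-out testing data the residual correlation is nonzero yet small
  r_test <- cor(log(analyte_values(halves$testing, "pb")) +
                  fit$b_opt * log(halves$testing$records$ufr),
                log(halves$testing$records$ufr))
  expect_false(identical(r_test, fit$r_opt))
  expect_lt(abs(r_test), 0.2)
})

test_that("the GM summary table covers all method-analyte cells with units", {
  ch <- generate_cohort(synthetic_params(n = 300, seed = 9))
  bt <- rbind(derive_b(ch, analytes = "pb"),
              derive_b(ch, analytes = "pb", criterion = "B"))
  tab <- adjustment_gm_table(ch, bt, osm_ref = 700, analytes = "pb")
  expect_setequal(tab$method, c("unadjusted", "creatinine", "osmolality",
                                "er", "erbw", "ufra", "ufrb"))
  expect_true(all(tab$gm > 0))
  expect_true(all(tab$min <= tab$gm & tab$gm <= tab$max))
  expect_match(tab$units[tab$method == "er"], "ng/hr")
})
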