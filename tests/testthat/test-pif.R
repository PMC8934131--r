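test_that("categorical PIF: identity, null association and the worked example", {
  p <- c(0.3850, 0.3081, 0.3069)
  rr <- c(1, 1.29, 1.54)
  expect_equal(pif_categorical(p, p, rr), 0)
  expect_equal(pif_categorical(p, c(1, 0, 0), c(1, 1, 1)), 0)

  # eliminate-excess scenario for endometrial cancer, females 45-54
  pif <- pif_categorical(p, c(1, 0, 0), rr)
  expect_equal(pif, 1 - 1 / (0.3850 + 0.3081 * 1.29 + 0.3069 * 1.54),
               tolerance = 1e-12)
  expect_equal(round(pif, 4), 0.2032)

  expect_error(pif_categorical(c(0.5, 0.2, 0.2), p, rr),
               class = "slt_validation_error")

  # ratio property: simultaneous rescaling of all RRs leaves the PIF unchanged
  set.seed(3)
  for (rep in 1:10) {
    pb <- as.numeric(rmultinom(1, 1000, runif(3))) / 1000
    pc <- as.numeric(rmultinom(1, 1000, runif(3))) / 1000
    r3 <- runif(3, 0.5, 3)
    kk <- runif(1, 0.1, 10)
    expect_equal(pif_categorical(pb, pc, r3), pif_categorical(pb, pc, kk * r3),
                 tolerance = 1e-12)
  }
})

test_that("PIF matches an individual-level simulation oracle", {
  set.seed(99)
  for (rep in 1:5) {
    pb <- as.numeric(rmultinom(1, 1e4, runif(3, 0.2, 1))) / 1e4
    pc <- as.numeric(rmultinom(1, 1e4, runif(3, 0.2, 1))) / 1e4
    rr <- c(1, runif(1, 1, 1.6), runif(1, 1, 2))
    n <- 1e6
    base_inc <- sum(rmultinom(1, n, pb) * 0.002 * rr)
    cf_inc <- sum(rmultinom(1, n, pc) * 0.002 * rr)
    expect_equal(pif_categorical(pb, pc, rr), 1 - cf_inc / base_inc,
                 tolerance = 5e-3)
  }
})

test_that("relative-risk shift follows the log-linear dose-response", {
  rr <- c(low = 1, moderate = 1.13, high = 1.31)
  anchors <- c(174, 348, 630)
  expect_equal(rr_shift_for_mean_change("high", rr, anchors, 0), 1.31)

  # full traversal of the high segment lands on the moderate RR
  expect_equal(rr_shift_for_mean_change("high", rr, anchors, 630 - 348), 1.13,
               tolerance = 1e-12)

  # worked arithmetic: 36.3 min off the high mean
  got <- rr_shift_for_mean_change("high", rr, anchors, 36.3)
  want <- exp(log(1.31) - (log(1.31) - log(1.13)) / (630 - 348) * 36.3)
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(got, 1.286, tolerance = 1e-3)

  # floor at the reference
  expect_equal(rr_shift_for_mean_change("moderate", rr, anchors, 1e5), 1)
  expect_equal(rr_shift_for_mean_change("low", rr, anchors, 50), 1)
  expect_error(rr_shift_for_mean_change("high", rr, c(400, 348, 630), 10),
               class = "slt_validation_error")
})

test_that("pif_for_scenario dispatches methods and honours dominance", {
  tab <- default_exposure_table()
  rrt <- default_rr_table()
  base <- exposure_stratum(tab, "female", "45-54")
  rr <- c(low = 1, moderate = 1.13, high = 1.31)

  no_change <- list(baseline = base, counterfactual = base, rr = rr, disease = "type2_diabetes")
  for (m in c("prevalence_shift", "rr_shift", "combined")) {
    expect_equal(pif_for_scenario(no_change, m)$pif, 0)
  }
  expect_error(pif_for_scenario(no_change, "bogus"))

  cf1 <- base; cf1$proportion <- c(1, 0, 0)
  cf2 <- exposure_stratum(apply_prevalence_shift(tab, "high", "moderate", 0.3),
                          "female", "45-54")
  p1 <- pif_for_scenario(list(baseline = base, counterfactual = cf1, rr = rr), "prevalence_shift")$pif
  p2 <- pif_for_scenario(list(baseline = base, counterfactual = cf2, rr = rr), "prevalence_shift")$pif
  expect_gte(p1, p2)

  cf4 <- exposure_stratum(apply_sitting_reduction(tab, 36.3), "female", "45-54")
  p4 <- pif_for_scenario(list(baseline = base, counterfactual = cf4, rr = rr), "rr_shift")$pif
  expect_gt(p4, 0)
  expect_lt(p4, p1)
})

test_that("pif_monte_carlo: degenerate inputs, reproducibility, convergence", {
  tab <- default_exposure_table()
  base <- exposure_stratum(tab, "female", "45-54")
  base$mean_se <- 0
  cf <- base; cf$proportion <- c(1, 0, 0)
  rr <- c(low = 1, moderate = 1.29, high = 1.54)
  input <- list(baseline = base, counterfactual = cf, rr = rr,
                disease = "endometrial_cancer")

  # all SEs zero -> every draw equals the deterministic PIF
  det <- pif_for_scenario(input, "prevalence_shift")$pif
  mc0 <- pif_monte_carlo(input, draws = 25, seed = 5)
  expect_true(all(mc0 == det))

  # fixed seed -> identical samples
  rr_ci <- data.frame(category = c("moderate", "high"),
                      ci_low = c(0.99, 1.29), ci_high = c(1.67, 1.83))
  s1 <- pif_monte_carlo(input, draws = 50, seed = 7, rr_ci = rr_ci)
  s2 <- pif_monte_carlo(input, draws = 50, seed = 7, rr_ci = rr_ci)
  expect_identical(s1, s2)

  # mean of 2000 draws vs an independent 200k-draw vectorised brute force
  s <- pif_monte_carlo(input, draws = 2000, seed = 11, rr_ci = rr_ci)
  set.seed(20260909)
  n <- 2e5
  rm_ <- pmax(rnorm(n, 1.29, (1.67 - 0.99) / (2 * Z)), 1e-6)
  rh_ <- pmax(rnorm(n, 1.54, (1.83 - 1.29) / (2 * Z)), 1e-6)
  denom <- base$proportion[1] + base$proportion[2] * rm_ + base$proportion[3] * rh_
  brute <- mean(1 - 1 / denom)  # counterfactual is all-low, rr_low = 1
  mc_se <- sd(s) / sqrt(length(s))
  expect_lt(abs(mean(s) - brute), 3 * mc_se)
})
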