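test_that("builtin scenarios encode the published policy definitions", {
  sc <- builtin_scenarios()
  expect_named(sc, c("1", "2", "3", "4"))
  expect_equal(sc[["2"]]$fraction_moved, 0.30)
  expect_equal(sc[["2"]]$from_cat, "high")
  expect_equal(sc[["2"]]$to_cat, "moderate")
  expect_equal(sc[["3"]]$fraction_moved, 0.30)
  expect_equal(sc[["3"]]$from_cat, "moderate")
  expect_equal(sc[["3"]]$to_cat, "low")
  expect_equal(sc[["4"]]$minutes_reduced, 36.3)
  expect_setequal(sc[["4"]]$target_categories, c("moderate", "high"))

  # scenario 1 sends every stratum to all-low
  cf <- sedlift:::counterfactual_exposure(sc[["1"]], default_exposure_table())
  expect_true(all(cf$proportion[cf$category == "low"] == 1))
  expect_true(all(cf$proportion[cf$category != "low"] == 0))

  expect_error(scenario_spec("x", "prevalence_shift"),
               class = "slt_validation_error")
  expect_error(scenario_spec("x", "sitting_reduction"),
               class = "slt_validation_error")
})

test_that("scenario 1 dominates scenarios 2-4 and the null is zero", {
  for (seed in c(21, 22)) {
    b <- make_bundle(seed = seed)
    sc <- builtin_scenarios()
    h <- vapply(sc, function(s) run_scenario(s, b)$totals[["halys_gained"]],
                numeric(1))
    expect_gte(h[["1"]], h[["2"]])
    expect_gte(h[["1"]], h[["3"]])
    expect_gte(h[["1"]], h[["4"]])
    expect_true(all(h > 0))
  }
  b <- make_bundle(seed = 23)
  null <- scenario_spec("null", "prevalence_shift", fraction_moved = 0,
                        from_cat = "high", to_cat = "moderate")
  expect_identical(unname(run_scenario(null, b)$totals), rep(0, 4))
})

test_that("scenario 4 equals a by-hand composition of the module operations", {
  b <- make_bundle(seed = 24)
  spec <- builtin_scenarios()[["4"]]
  got <- run_scenario(spec, b)

  # recompute the PIF table by chaining the public operations directly
  reduced <- apply_sitting_reduction(b$exposure, 36.3, c("moderate", "high"))
  rows <- list()
  for (sex in c("female", "male")) {
    for (band in unique(b$exposure$age_band)) {
      base <- exposure_stratum(b$exposure, sex, band)
      red <- exposure_stratum(reduced, sex, band)
      for (d in names(b$epi)) {
        if (d %in% c("breast_cancer", "endometrial_cancer") && sex == "male") next
        rr <- setNames(b$rr$rr[b$rr$disease == d][match(c("low", "moderate", "high"),
                b$rr$category[b$rr$disease == d])], c("low", "moderate", "high"))
        rr_cf <- rr
        for (cat in c("moderate", "high")) {
          delta <- base$mean_minutes[base$category == cat] -
            red$mean_minutes[red$category == cat]
          rr_cf[[cat]] <- rr_shift_for_mean_change(cat, rr, base$mean_minutes, delta)
        }
        num <- sum(base$proportion * rr) - sum(base$proportion * rr_cf)
        rows[[length(rows) + 1]] <- data.frame(
          sex = sex, age_band = band, disease = d,
          pif = num / sum(base$proportion * rr))
      }
    }
  }
  manual_pifs <- do.call(rbind, rows)
  state <- build_model(b$pop, b$epi, b$costs)
  want <- run_comparison(state, manual_pifs)
  expect_equal(got$totals, want$totals, tolerance = 1e-12)
  expect_equal(got$by, want$by, tolerance = 1e-12)
})

test_that("average-reduction reporting honours both target conventions", {
  tab <- default_exposure_table()
  sc <- builtin_scenarios()

  lm <- scenario_average_reduction(sc[["1"]], tab, "low_mean")
  cap <- scenario_average_reduction(sc[["1"]], tab, "cap")
  hi_lm <- lm$minutes_reduced[lm$category == "high"]
  hi_cap <- cap$minutes_reduced[cap$category == "high"]
  # movers to the low-category mean lose more minutes than movers to the cap
  expect_true(all(hi_lm > hi_cap))
  hi_rows <- lm[lm$category == "high", ]
  sel <- hi_rows$sex == "female" & hi_rows$age_band == "45-54"
  expect_equal(hi_cap[sel], 618.50 - 240)
  expect_equal(hi_lm[sel], 618.50 - 163.02)

  # sitting-reduction scenarios report the flat (possibly floored) reduction
  s4 <- scenario_average_reduction(sc[["4"]], tab)
  expect_true(all(s4$minutes_reduced == 36.3))

  # PIFs are unaffected by the convention (prevalence shifts ignore means)
  expect_identical(scenario_pifs(sc[["1"]], tab, default_rr_table()),
                   scenario_pifs(sc[["1"]], tab, default_rr_table()))
})

test_that("coverage threshold analysis inverts the forward model", {
  b <- make_bundle(seed = 25)
  spec <- scenario_spec("t", "sitting_reduction", minutes_reduced = 36.3)
  state <- build_model(b$pop, b$epi, b$costs)
  halys_at <- function(cov) {
    run_comparison(state, scenario_pifs(spec, b$exposure, b$rr, coverage = cov)
                   )$totals[["halys_gained"]]
  }
  target <- halys_at(0.5)
  res <- threshold_coverage(36.3, target, b)
  expect_true(res$converged)
  expect_equal(res$coverage, 0.5, tolerance = 1e-3)
  expect_equal(res$achieved_halys, target, tolerance = 1e-3 * target)

  # unreachable target
  res2 <- threshold_coverage(36.3, halys_at(1) * 10, b)
  expect_false(res2$converged)
  expect_equal(res2$coverage, 1)

  # HALYs strictly increasing in coverage and in minutes reduced
  covs <- c(0.2, 0.5, 0.8, 1)
  expect_true(all(diff(vapply(covs, halys_at, numeric(1))) > 0))
  hmins <- vapply(c(10, 36.3, 60), function(m) {
    sp <- scenario_spec("m", "sitting_reduction", minutes_reduced = m)
    run_comparison(state, scenario_pifs(sp, b$exposure, b$rr))$totals[["halys_gained"]]
  }, numeric(1))
  expect_true(all(diff(hmins) > 0))
})
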