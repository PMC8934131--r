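test_that("build_model validates grids and degenerate inputs", {
  b <- make_bundle(seed = 1)
  state <- build_model(b$pop, b$epi, b$costs)
  expect_s3_class(state, "slt_model")
  expect_equal(length(state$epi), 5)
  expect_equal(length(state$ages), 31)

  # empty disease list: general mortality only
  empty <- build_model(b$pop, list(), NULL)
  out <- run_comparison(empty, data.frame())
  expect_equal(unname(out$totals), rep(0, 4))

  # missing top ages in one disease's grid is an error naming the disease
  broken <- b$epi
  broken$stroke <- broken$stroke[broken$stroke$age < 70, ]
  expect_error(build_model(b$pop, broken, b$costs), "stroke",
               class = "slt_validation_error")
})

test_that("cost loading applies inflation and enforces the cost basis", {
  df <- data.frame(disease = c("colorectal_cancer", "type2_diabetes"),
                   sex = "all", age_band = "all",
                   cost_basis = c("per_incident_case", "per_prevalent_case"),
                   cost_aud = c(1000, 3000))
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  expect_equal(load_costs(f)$cost_aud, c(1000, 3000))
  expect_equal(load_costs(f, inflation_index = 1.10)$cost_aud, c(1100, 3300))

  bad <- df
  bad$cost_basis <- rev(bad$cost_basis)  # per-incident disease given per-prevalent rows
  write.csv(bad, f, row.names = FALSE)
  expect_error(load_costs(f), class = "slt_validation_error")

  neg <- df
  neg$cost_aud[1] <- -5
  write.csv(neg, f, row.names = FALSE)
  expect_error(load_costs(f), class = "slt_validation_error")
})

test_that("null scenario returns exact zeros and intact life-table columns", {
  b <- make_bundle(seed = 2)
  state <- build_model(b$pop, b$epi, b$costs)
  zero_pifs <- scenario_pifs(
    scenario_spec("null", "prevalence_shift", fraction_moved = 0,
                  from_cat = "high", to_cat = "moderate"),
    b$exposure, b$rr)
  expect_true(all(zero_pifs$pif == 0))
  out <- run_comparison(state, zero_pifs, horizon_years = 5, detail = TRUE)
  expect_identical(unname(out$totals), rep(0, 4))
  expect_true(all(out$by$halys_gained == 0))
  for (sex in names(out$detail)) {
    det <- out$detail[[sex]]
    expect_true(all(diff(det$l_bau) <= 0))       # survivors non-increasing
    expect_true(all(det$Lw_bau <= det$L_bau + 1e-12))
    expect_identical(det$l_bau, det$l_scn)
  }
})

test_that("outputs are linear in population and conserve disaggregations", {
  b <- make_bundle(seed = 3)
  state <- build_model(b$pop, b$epi, b$costs)
  pifs <- scenario_pifs(builtin_scenarios()[["2"]], b$exposure, b$rr)
  out <- run_comparison(state, pifs, horizon_years = 3, discount_rate = 0.03)

  b2 <- b
  b2$pop$population <- b2$pop$population * 2
  out2 <- run_comparison(build_model(b2$pop, b2$epi, b2$costs), pifs,
                         horizon_years = 3, discount_rate = 0.03)
  expect_equal(out2$totals, 2 * out$totals, tolerance = 1e-12)

  # disaggregations sum to totals (exact attribution)
  for (m in names(out$totals)) {
    expect_equal(sum(out$by[[m]]), out$totals[[m]], tolerance = 1e-9)
    expect_equal(sum(out$by_sex[[m]]), out$totals[[m]], tolerance = 1e-9)
    expect_equal(sum(out$by_disease[[m]]), out$totals[[m]], tolerance = 1e-9)
  }
})

test_that("zero disability weights and costs reduce HALYs to life-years", {
  b <- make_bundle(seed = 4)
  b$pop$total_yld_rate <- 0
  for (d in names(b$epi)) {
    b$epi[[d]]$disability_weight <- 0
    b$epi[[d]]$yld_rate <- 0
  }
  b$costs$cost_aud <- 0
  state <- build_model(b$pop, b$epi, b$costs)
  pifs <- scenario_pifs(builtin_scenarios()[["1"]], b$exposure, b$rr)
  out <- run_comparison(state, pifs, horizon_years = 4, detail = TRUE)
  expect_identical(out$totals[["cost_offset"]], 0)
  ly_gain <- sum(vapply(out$detail, function(det) {
    sum(det$L_scn - det$L_bau)
  }, numeric(1)))
  expect_equal(out$totals[["halys_gained"]], ly_gain, tolerance = 1e-9)
  # with w = 0, Lw equals L exactly
  for (det in out$detail) expect_identical(det$Lw_bau, det$L_bau)
})

test_that("HALY gains are monotone in each PIF", {
  b <- make_bundle(seed = 6)
  state <- build_model(b$pop, b$epi, b$costs)
  pifs <- scenario_pifs(builtin_scenarios()[["2"]], b$exposure, b$rr)
  base_h <- run_comparison(state, pifs)$totals[["halys_gained"]]
  set.seed(10)
  for (rep in 1:5) {
    k <- sample(nrow(pifs), 1)
    up <- pifs
    up$pif[k] <- min(up$pif[k] + runif(1, 0.05, 0.3), 1)
    expect_gte(run_comparison(state, up)$totals[["halys_gained"]], base_h)
  }
  expect_error(run_comparison(state, transform(pifs, disease = "gout")),
               class = "slt_validation_error")
})
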