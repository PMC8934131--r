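# Synthetic input bundles.
#
# The real model inputs (survey microdata, global burden-of-disease
# extractions, national expenditure tables) are not redistributable, so the
# generator emulates their statistical structure: a smooth adult population
# pyramid with Gompertz all-cause mortality, unimodal age-specific disease
# incidence, and prevalence derived *forward* through the illness-death engine
# (never drawn independently) so internal consistency holds exactly by
# construction.  Default magnitudes are chosen so scenario outputs land at
# O(10^3) HALYs for an adult population of ~2 x 10^7 — the same order as the
# published national model — with no claim of matching its tables.

#' Synthetic-bundle configuration
#'
#' @param seed mandatory integer seed; one seed gives byte-identical bundles.
#' @param ages modelled age range (default 18:100).
#' @param gompertz_a,gompertz_b all-cause mortality `m(x) = a * exp(b * x)`,
#'   capped at 1.  Defaults approximate a modern high-income schedule
#'   (m(40) ~ 1e-3, m(80) ~ 0.04).
#' @param total_population adults across both sexes (default 1.95e7).
#' @param exposure_concentration Dirichlet-type concentration for category
#'   proportions around survey-like centres (larger = closer to the centres).
#' @param study_k studies per synthetic meta-analysis.
#' @param true_log_rr,tau meta-analysis truth: study log-RRs are
#'   `Normal(true_log_rr, tau^2)` plus within-study noise.
#' @param disease_params per-disease data.frame; see
#'   [default_synth_disease_params()].
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed, ages = 18:100, gompertz_a = 2.7e-5,
                         gompertz_b = 0.09, total_population = 1.95e7,
                         exposure_concentration = 300, study_k = 6,
                         true_log_rr = 0.27, tau = 0.10,
                         disease_params = default_synth_disease_params()) {
  if (missing(seed)) abort_validation("synth_config requires an explicit seed")
  if (gompertz_a < 0 || gompertz_b < 0) abort_validation("Gompertz parameters must be >= 0")
  if (tau < 0 || study_k < 1) abort_validation("invalid meta-analysis truth parameters")
  structure(list(seed = as.integer(seed), ages = as.integer(ages),
                 gompertz_a = gompertz_a, gompertz_b = gompertz_b,
                 total_population = total_population,
                 exposure_concentration = exposure_concentration,
                 study_k = as.integer(study_k), true_log_rr = true_log_rr,
                 tau = tau, disease_params = disease_params),
            class = "synth_config")
}

#' Default synthetic disease parameters
#'
#' Incidence is a Gaussian bump in age peaking at `incidence_peak_age` with
#' height `incidence_peak_rate`; case fatality is constant in age;
#' disability weights are in the range used by burden-of-disease studies.
#'
#' @return data.frame with one row per disease.
#' @export
default_synth_disease_params <- function() {
  data.frame(
    name = c("type2_diabetes", "stroke", "breast_cancer",
             "colorectal_cancer", "endometrial_cancer"),
    incidence_peak_age = c(62, 82, 64, 74, 67),
    incidence_peak_rate = c(8e-3, 9e-3, 3e-3, 2e-3, 1e-3),
    incidence_width = c(22, 16, 18, 16, 12),
    case_fatality_rate = c(0.015, 0.06, 0.04, 0.08, 0.05),
    disability_weight = c(0.07, 0.32, 0.22, 0.19, 0.21),
    cost_per_case = c(3000, 9000, 12000, 40000, 30000)
  )
}

#' Generate a synthetic population table
#'
#' Smooth declining pyramid over `cfg$ages`, split evenly by sex, with
#' Gompertz all-cause mortality and a background morbidity (years-lived-with-
#' disability) rate rising linearly with age from 0.05 to 0.15.
#'
#' @param cfg a [synth_config()].
#' @return population data.frame (see [load_population()]).
#' @export
generate_population <- function(cfg) {
  ages <- cfg$ages
  shape <- exp(-0.015 * (ages - min(ages)))
  n_age <- cfg$total_population / 2 * shape / sum(shape)
  m <- pmin(cfg$gompertz_a * exp(cfg$gompertz_b * ages), 1)
  w <- 0.05 + 0.10 * (ages - min(ages)) / max(max(ages) - min(ages), 1)
  do.call(rbind, lapply(SEXES, function(sex) {
    data.frame(sex = sex, age = ages, population = n_age,
               all_cause_mortality = m, total_yld_rate = w)
  }))
}

#' Generate internally consistent synthetic disease epidemiology
#'
#' Incidence is a smooth unimodal curve in age; prevalence and the implied
#' disease mortality are derived through [solve_illness_death()] with the
#' population's all-cause mortality as the background rate, so the bundle
#' satisfies the illness-death consistency property to machine precision.
#' `yld_rate = prevalence * disability_weight`.
#'
#' @param cfg a [synth_config()].
#' @param disease one of the five modelled disease names.
#' @param population optional population table (generated from `cfg` if
#'   absent) supplying the background mortality.
#' @return disease epi data.frame (see [load_disease_epi()]).
#' @export
generate_disease_epi <- function(cfg, disease, population = NULL) {
  pars <- cfg$disease_params[cfg$disease_params$name == disease, ]
  if (!nrow(pars)) abort_validation(sprintf("no synthetic parameters for %s", disease))
  population <- population %||% generate_population(cfg)
  defs <- default_disease_definitions()
  ages <- cfg$ages
  inc <- pars$incidence_peak_rate *
    exp(-((ages - pars$incidence_peak_age) / pars$incidence_width)^2)
  out <- lapply(disease_sexes(defs, disease), function(sex) {
    m_other <- population$all_cause_mortality[population$sex == sex]
    sol <- solve_illness_death(inc, pars$case_fatality_rate, 0, m_other,
                               start_age = min(ages), end_age = max(ages))
    data.frame(disease = disease, sex = sex, age = ages, incidence = inc,
               prevalence = sol$p, case_fatality = pars$case_fatality_rate,
               remission = 0,
               yld_rate = sol$p * pars$disability_weight,
               disability_weight = pars$disability_weight)
  })
  do.call(rbind, out)
}

#' Generate a synthetic sitting-time exposure table
#'
#' Per-stratum category proportions are drawn from a Dirichlet distribution
#' around survey-like centres (low/moderate/high roughly 30/36/34%); category
#' means are drawn uniformly inside their category bounds and kept strictly
#' ordered.  As the concentration grows the proportions converge to the
#' centres.
#'
#' @param cfg a [synth_config()].
#' @return an `exposure_table`.
#' @export
generate_exposure <- function(cfg) {
  set.seed(draw_seed(cfg$seed, 11L))
  centres <- c(low = 0.30, moderate = 0.36, high = 0.34)
  conc <- cfg$exposure_concentration
  rows <- list()
  for (sex in SEXES) {
    for (band in AGE_BANDS) {
      g <- rgamma(3, shape = conc * centres)
      p <- g / sum(g)
      means <- c(runif(1, 150, 225), runif(1, 330, 370), runif(1, 600, 700))
      rows[[length(rows) + 1]] <- data.frame(
        sex = sex, age_band = band, category = SB_LEVELS,
        proportion = p, proportion_se = pmin(0.05 * p + 0.005, 0.05),
        mean_minutes = means, mean_se = c(4, 3.5, 12))
    }
  }
  validate_exposure_table(do.call(rbind, rows))
}

#' Generate synthetic study effects for meta-analysis tests
#'
#' Study log-RRs are `Normal(true_log_rr, tau^2)` plus within-study
#' `Normal(0, se^2)` noise with `se ~ U(0.05, 0.15)`; 95% CIs are
#' back-computed from the same `se`, so [pool_random_effects_reml()] can be
#' exercised against a known truth.
#'
#' @param cfg a [synth_config()].
#' @param disease,contrast labels copied onto the studies.
#' @return data.frame `study_id, disease, contrast, rr, ci_low, ci_high`.
#' @export
generate_study_effects <- function(cfg, disease = "type2_diabetes",
                                   contrast = "high_vs_low") {
  set.seed(draw_seed(cfg$seed, 13L))
  k <- cfg$study_k
  se <- runif(k, 0.05, 0.15)
  theta <- rnorm(k, cfg$true_log_rr, cfg$tau)
  y <- rnorm(k, theta, se)
  data.frame(study_id = sprintf("synth_%02d", seq_len(k)),
             disease = disease, contrast = contrast,
             rr = exp(y), ci_low = exp(y - Z95 * se), ci_high = exp(y + Z95 * se))
}

#' Generate a complete synthetic input bundle
#'
#' Population, the five disease epidemiology tables (consistent by
#' construction), a synthetic exposure table, per-case costs from the default
#' disease parameters, and the packaged pooled relative-risk fixture.
#'
#' @param cfg a [synth_config()].
#' @return list of class `slt_inputs`: `exposure, rr, pop, epi, costs, defs,
#'   config`.
#' @export
generate_bundle <- function(cfg) {
  pop <- generate_population(cfg)
  defs <- default_disease_definitions()
  epi <- setNames(lapply(defs$name, generate_disease_epi, cfg = cfg,
                         population = pop), defs$name)
  costs <- data.frame(disease = defs$name, sex = "all", age_band = "all",
                      cost_basis = defs$cost_basis,
                      cost_aud = cfg$disease_params$cost_per_case[
                        match(defs$name, cfg$disease_params$name)])
  structure(list(exposure = generate_exposure(cfg), rr = default_rr_table(),
                 pop = pop, epi = epi, costs = costs, defs = defs,
                 config = cfg),
            class = "slt_inputs")
}

#' Write a bundle to a directory of CSV files plus a manifest
#'
#' Files: `population.csv`, `disease_epi.csv`, `exposure.csv`, `costs.csv`,
#' `rr.csv`, `study_effects.csv` and `manifest.json` (seed and configuration
#' echo).  Output is byte-identical for a given seed.
#'
#' @param bundle an `slt_inputs` bundle from [generate_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) write.csv(df, file.path(dir, name), row.names = FALSE)
  wr(bundle$pop, "population.csv")
  wr(do.call(rbind, bundle$epi), "disease_epi.csv")
  wr(as.data.frame(bundle$exposure), "exposure.csv")
  wr(bundle$costs, "costs.csv")
  wr(as.data.frame(bundle$rr), "rr.csv")
  cfg <- bundle$config
  if (!is.null(cfg)) {
    wr(generate_study_effects(cfg), "study_effects.csv")
    jsonlite::write_json(
      list(seed = cfg$seed, ages = range(cfg$ages),
           gompertz = c(a = cfg$gompertz_a, b = cfg$gompertz_b),
           total_population = cfg$total_population,
           exposure_concentration = cfg$exposure_concentration,
           study_k = cfg$study_k, true_log_rr = cfg$true_log_rr, tau = cfg$tau,
           package_version = as.character(utils::packageVersion("sedlift"))),
      file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a bundle directory written by [write_bundle()]
#' @param dir bundle directory.
#' @return an `slt_inputs` bundle.
#' @export
read_bundle <- function(dir) {
  structure(list(
    exposure = load_exposure_table(file.path(dir, "exposure.csv")),
    rr = load_rr_table(file.path(dir, "rr.csv")),
    pop = load_population(file.path(dir, "population.csv")),
    epi = load_disease_epi(file.path(dir, "disease_epi.csv")),
    costs = load_costs(file.path(dir, "costs.csv")),
    defs = default_disease_definitions()
  ), class = "slt_inputs")
}
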