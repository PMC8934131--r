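# Potential impact fractions from categorical exposure distributions.
#
# Scenarios 1-3 change the category proportions (prevalence shift); scenario 4
# keeps proportions fixed and moves category relative risks along a piecewise
# log-linear dose-response anchored at the category mean sitting times
# (relative-risk shift).

#' Categorical potential impact fraction
#'
#' `PIF = (sum(p_base * rr) - sum(p_cf * rr)) / sum(p_base * rr)`; the
#' proportional change in disease incidence when the exposure distribution
#' moves from `p_base` to `p_cf` with fixed category relative risks.
#'
#' @param p_base,p_cf category proportion vectors, each summing to 1.
#' @param rr per-category relative risks (> 0), reference category = 1.
#' @return fraction <= 1 (negative for harmful shifts).
#' @examples
#' pif_categorical(c(0.3850, 0.3081, 0.3069), c(1, 0, 0), c(1, 1.29, 1.54))
#' @export
pif_categorical <- function(p_base, p_cf, rr) {
  pif_general(p_base, rr, p_cf, rr)
}

# generalised form allowing the counterfactual to carry its own RR vector
# (used by the relative-risk shift, where proportions stay put but RRs move)
pif_general <- function(p_base, rr_base, p_cf, rr_cf) {
  if (abs(sum(p_base) - 1) > 1e-6 || abs(sum(p_cf) - 1) > 1e-6) {
    abort_validation("proportion vectors must sum to 1")
  }
  if (any(rr_base <= 0) || any(rr_cf <= 0)) {
    abort_validation("relative risks must be > 0")
  }
  base <- sum(p_base * rr_base)
  (base - sum(p_cf * rr_cf)) / base
}

#' Shift a category relative risk for a within-category mean change
#'
#' Assumes a piecewise log-linear dose-response through the anchor points
#' `(mean_low, log 1)`, `(mean_moderate, log rr_moderate)`,
#' `(mean_high, log rr_high)`.  Reducing a category's mean sitting time by
#' `delta_minutes` moves its RR down its own segment:
#' `log rr' = log rr - slope(category) * delta_minutes`, with
#' `slope(moderate) = log(rr_m) / (mean_m - mean_l)` and
#' `slope(high) = (log(rr_h) - log(rr_m)) / (mean_h - mean_m)`.
#' The result is floored at 1 (no protective extrapolation below reference).
#'
#' @param category `"moderate"` or `"high"` (`"low"` returns 1 unchanged).
#' @param rr length-3 RR vector `(low = 1, moderate, high)`.
#' @param anchor_means strictly increasing category mean minutes/day.
#' @param delta_minutes reduction in the category mean (>= 0).
#' @return the shifted relative risk for that category.
#' @export
rr_shift_for_mean_change <- function(category, rr, anchor_means, delta_minutes) {
  if (delta_minutes < 0) abort_domain("delta_minutes must be >= 0")
  if (!(anchor_means[1] < anchor_means[2] && anchor_means[2] < anchor_means[3])) {
    abort_validation("anchor means must be strictly increasing")
  }
  if (category == "low") return(1)
  slope <- switch(category,
    moderate = log(rr[[2]]) / (anchor_means[2] - anchor_means[1]),
    high = (log(rr[[3]]) - log(rr[[2]])) / (anchor_means[3] - anchor_means[2]),
    abort_domain(sprintf("unknown category '%s'", category)))
  cur <- switch(category, moderate = rr[[2]], high = rr[[3]])
  max(exp(log(cur) - slope * delta_minutes), 1)
}

# full shifted RR vector for a stratum given per-category mean reductions
shift_rrs <- function(rr, anchor_means, deltas) {
  out <- rr
  for (cat in c("moderate", "high")) {
    d <- deltas[[cat]] %||% 0
    if (d > 0) {
      out[[cat]] <- rr_shift_for_mean_change(cat, rr, anchor_means, d)
    }
  }
  out
}

#' Potential impact fraction for one stratum and disease
#'
#' @param input list with elements `baseline` and `counterfactual` (3-row
#'   stratum slices, see [exposure_stratum()]), `rr` (length-3 named RR
#'   vector), and optionally `sex`, `age_band`, `disease` labels.
#' @param method `"prevalence_shift"` (use the two proportion vectors),
#'   `"rr_shift"` (unchanged proportions, RRs moved by the baseline-minus-
#'   counterfactual category mean changes along the dose-response), or
#'   `"combined"` (both).
#' @return one-row data.frame `sex, age_band, disease, pif`.
#' @export
pif_for_scenario <- function(input,
                             method = c("prevalence_shift", "rr_shift", "combined")) {
  method <- match.arg(method)
  base <- input$baseline
  cf <- input$counterfactual
  if (!identical(base$sex, cf$sex) || !identical(base$age_band, cf$age_band)) {
    abort_validation("baseline and counterfactual must describe the same stratum")
  }
  rr <- input$rr
  deltas <- as.list(setNames(pmax(base$mean_minutes - cf$mean_minutes, 0), base$category))
  pif <- switch(method,
    prevalence_shift = pif_general(base$proportion, rr, cf$proportion, rr),
    rr_shift = pif_general(base$proportion, rr, base$proportion,
                           shift_rrs(rr, base$mean_minutes, deltas)),
    combined = pif_general(base$proportion, rr, cf$proportion,
                           shift_rrs(rr, base$mean_minutes, deltas)))
  data.frame(sex = base$sex[1] %||% NA_character_,
             age_band = base$age_band[1] %||% NA_character_,
             disease = input$disease %||% NA_character_,
             pif = pif)
}

# lognormal (meanlog, sdlog) matched to an arithmetic mean and sd
lnorm_params <- function(mean, sd) {
  sigma2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Monte-Carlo sample of a stratum/disease PIF
#'
#' Per draw, category relative risks are sampled via [rr_sampling_params()]
#' (normal on the natural scale, truncated below at `1e-6`) and category mean
#' sitting times from a moment-matched lognormal; the deterministic PIF is
#' then evaluated at the sampled parameters.  All randomness is a function of
#' `(seed, draw index)`, so a fixed seed reproduces the sample exactly.
#'
#' @inheritParams pif_for_scenario
#' @param draws number of draws (>= 1).
#' @param seed integer RNG seed.
#' @param rr_ci data.frame `category, ci_low, ci_high` giving the 95% CIs of
#'   the non-reference RRs (zero-width for fixed categories); defaults to the
#'   degenerate point-mass case.
#' @param rr_scale `"natural"` or `"log"` sampling scale.
#' @return numeric vector of `draws` PIF values.
#' @export
pif_monte_carlo <- function(input, draws, seed,
                            method = c("prevalence_shift", "rr_shift", "combined"),
                            rr_ci = NULL, rr_scale = c("natural", "log")) {
  method <- match.arg(method)
  rr_scale <- match.arg(rr_scale)
  if (draws < 1) abort_domain("draws must be >= 1")
  base <- input$baseline
  out <- numeric(draws)
  for (j in seq_len(draws)) {
    set.seed(draw_seed(seed, j))
    inp_j <- input
    inp_j$rr <- sample_rr_vector(input$rr, rr_ci, rr_scale)
    means <- sample_means(base$mean_minutes, base$mean_se)
    inp_j$baseline$mean_minutes <- means
    inp_j$counterfactual$mean_minutes <-
      pmax(means - (base$mean_minutes - input$counterfactual$mean_minutes), 0)
    out[j] <- pif_for_scenario(inp_j, method)$pif
  }
  out
}

# sample a named RR vector given CI half-widths; zero-width CI => point mass
sample_rr_vector <- function(rr, rr_ci, rr_scale) {
  if (is.null(rr_ci)) return(rr)
  out <- rr
  for (i in seq_len(nrow(rr_ci))) {
    cat <- rr_ci$category[i]
    pr <- rr_sampling_params(rr[[cat]], rr_ci$ci_low[i], rr_ci$ci_high[i], rr_scale)
    if (pr[["spread"]] == 0) next
    out[[cat]] <- if (rr_scale == "natural") {
      max(rnorm(1, pr[["location"]], pr[["spread"]]), 1e-6)
    } else {
      exp(rnorm(1, pr[["location"]], pr[["spread"]]))
    }
  }
  out
}

# sample category mean minutes from moment-matched lognormals, kept ordered
sample_means <- function(means, ses) {
  out <- means
  for (i in seq_along(means)) {
    if (ses[i] > 0) {
      lp <- lnorm_params(means[i], ses[i])
      out[i] <- rlnorm(1, lp[["meanlog"]], lp[["sdlog"]])
    }
  }
  # survey SEs are tiny relative to the gaps between category means, so
  # crossings are essentially impossible; enforce strict ordering defensively
  if (is.unsorted(out, strictly = TRUE)) {
    out <- sort(out) + (seq_along(out) - 1) * 1e-9
  }
  out
}
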