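# Scenario definitions and end-to-end runs.
#
# Scenario 1: everyone in the moderate and high categories moves to low.
# Scenario 2: 30% of the high category moves to moderate.
# Scenario 3: 30% of the moderate category moves to low.
# Scenario 4: sitting time falls by 36.3 min/day in the moderate and high
#             categories (relative-risk shift), the effect size observed in a
#             12-month multi-component workplace trial.
# Coverage scales the affected fraction of the target population; because the
# categorical PIF is linear in the mixed counterfactual, coverage acts as an
# exact linear multiplier on every stratum PIF.

#' Construct a scenario specification
#'
#' @param id label.
#' @param kind `"eliminate_excess"`, `"prevalence_shift"`,
#'   `"sitting_reduction"` or `"threshold"`.
#' @param fraction_moved fraction in `[0, 1]` (prevalence_shift).
#' @param from_cat,to_cat categories for a prevalence shift.
#' @param minutes_reduced minutes/day (sitting_reduction / threshold).
#' @param target_categories categories receiving the sitting reduction.
#' @param target_halys HALY target (threshold).
#' @param coverage fraction of the target population affected (default 1).
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(id, kind, fraction_moved = NULL, from_cat = NULL,
                          to_cat = NULL, minutes_reduced = NULL,
                          target_categories = c("moderate", "high"),
                          target_halys = NULL, coverage = 1) {
  kind <- match.arg(kind, c("eliminate_excess", "prevalence_shift",
                            "sitting_reduction", "threshold"))
  if (coverage < 0 || coverage > 1) abort_domain("coverage must lie in [0, 1]")
  if (kind == "prevalence_shift" &&
      (is.null(fraction_moved) || is.null(from_cat) || is.null(to_cat))) {
    abort_validation("prevalence_shift needs fraction_moved, from_cat, to_cat")
  }
  if (kind %in% c("sitting_reduction", "threshold") && is.null(minutes_reduced)) {
    abort_validation(sprintf("%s needs minutes_reduced", kind))
  }
  if (kind == "threshold" && is.null(target_halys)) {
    abort_validation("threshold needs target_halys")
  }
  structure(list(id = id, kind = kind, fraction_moved = fraction_moved,
                 from_cat = from_cat, to_cat = to_cat,
                 minutes_reduced = minutes_reduced,
                 target_categories = target_categories,
                 target_halys = target_halys, coverage = coverage),
            class = "scenario_spec")
}

#' The four built-in scenarios
#' @return named list of `scenario_spec` objects (`"1"` to `"4"`).
#' @export
builtin_scenarios <- function() {
  list(
    "1" = scenario_spec("1", "eliminate_excess"),
    "2" = scenario_spec("2", "prevalence_shift", fraction_moved = 0.30,
                        from_cat = "high", to_cat = "moderate"),
    "3" = scenario_spec("3", "prevalence_shift", fraction_moved = 0.30,
                        from_cat = "moderate", to_cat = "low"),
    "4" = scenario_spec("4", "sitting_reduction", minutes_reduced = 36.3,
                        target_categories = c("moderate", "high"))
  )
}

# counterfactual exposure table implied by a spec (coverage handled later)
counterfactual_exposure <- function(spec, exposure) {
  switch(spec$kind,
    eliminate_excess = {
      cf <- exposure
      key <- paste(cf$sex, cf$age_band)
      for (k in unique(key)) {
        idx <- key == k
        cf$proportion[idx] <- ifelse(cf$category[idx] == "low", 1, 0)
      }
      cf
    },
    prevalence_shift = apply_prevalence_shift(exposure, spec$from_cat,
                                              spec$to_cat, spec$fraction_moved),
    sitting_reduction = ,
    threshold = apply_sitting_reduction(exposure, spec$minutes_reduced,
                                        spec$target_categories)
  )
}

# PIF method a spec uses
scenario_method <- function(spec) {
  if (spec$kind %in% c("sitting_reduction", "threshold")) "rr_shift"
  else "prevalence_shift"
}

#' Stratum x disease potential impact fractions for a scenario
#'
#' @param spec a `scenario_spec`.
#' @param exposure baseline `exposure_table`.
#' @param rr_table an `rr_table` of per-category relative risks.
#' @param defs disease definitions (restricts female-only diseases).
#' @param coverage overrides `spec$coverage` when given.
#' @return data.frame `sex, age_band, disease, pif`.
#' @export
scenario_pifs <- function(spec, exposure, rr_table, defs = default_disease_definitions(),
                          coverage = NULL) {
  coverage <- coverage %||% spec$coverage
  cf_table <- counterfactual_exposure(spec, exposure)
  method <- scenario_method(spec)
  diseases <- intersect(defs$name, unique(rr_table$disease))
  strata <- unique(exposure[c("sex", "age_band")])
  out <- vector("list", nrow(strata) * length(diseases))
  k <- 0
  for (s in seq_len(nrow(strata))) {
    sex <- strata$sex[s]
    band <- strata$age_band[s]
    base <- exposure_stratum(exposure, sex, band)
    cf <- exposure_stratum(cf_table, sex, band)
    for (d in diseases) {
      if (!sex %in% disease_sexes(defs, d)) next
      k <- k + 1
      res <- pif_for_scenario(list(baseline = base, counterfactual = cf,
                                   rr = rr_vector(rr_table, d), disease = d),
                              method)
      res$pif <- coverage * res$pif
      out[[k]] <- res
    }
  }
  do.call(rbind, out[seq_len(k)])
}

#' Average sitting-time reduction implied by a scenario
#'
#' The published scenario narratives quote an "average reduction" in daily
#' sitting for the affected group, but two target conventions are possible for
#' movers in a prevalence shift: they adopt the destination category's
#' existing mean (`"low_mean"`, the model's working assumption) or they sit at
#' the destination category's boundary (`"cap"`, e.g. 240 min for moves to the
#' low category).  The choice does not change any PIF (prevalence-shift PIFs
#' never use the means), only this descriptive statistic; both are exposed and
#' neither is asserted as the published intent.
#'
#' @param spec a `scenario_spec`.
#' @param exposure baseline `exposure_table`.
#' @param convention `"low_mean"` or `"cap"`.
#' @return data.frame `sex, age_band, category, minutes_reduced` giving the
#'   per-mover (or per-member, for sitting reductions) reduction in each
#'   source category.
#' @export
scenario_average_reduction <- function(spec, exposure,
                                       convention = c("low_mean", "cap")) {
  convention <- match.arg(convention)
  cats <- sb_categories()
  strata <- unique(exposure[c("sex", "age_band")])
  moves <- switch(spec$kind,
    eliminate_excess = list(c("moderate", "low"), c("high", "low")),
    prevalence_shift = list(c(spec$from_cat, spec$to_cat)),
    sitting_reduction = ,
    threshold = lapply(spec$target_categories, function(cat) c(cat, cat)))
  rows <- list()
  for (s in seq_len(nrow(strata))) {
    st <- exposure_stratum(exposure, strata$sex[s], strata$age_band[s])
    for (mv in moves) {
      from <- mv[1]; to <- mv[2]
      red <- if (from == to) {
        min(spec$minutes_reduced,
            st$mean_minutes[st$category == from] - cats$lower[cats$name == from])
      } else {
        target <- if (convention == "low_mean") {
          st$mean_minutes[st$category == to]
        } else {
          cats$upper[cats$name == to]
        }
        max(st$mean_minutes[st$category == from] - target, 0)
      }
      rows[[length(rows) + 1]] <- data.frame(
        sex = strata$sex[s], age_band = strata$age_band[s], category = from,
        minutes_reduced = red)
    }
  }
  do.call(rbind, rows)
}

#' Run a scenario end to end
#'
#' Builds the counterfactual exposure, computes per-stratum/disease PIFs,
#' and evaluates the proportional multi-state life table.  With `mc` an
#' [mc_config()], wraps the run in second-order Monte-Carlo sampling and
#' returns a summary with 95% uncertainty intervals; otherwise returns the
#' deterministic `slt_output`.  The sitting-time change is assumed sustained
#' over the whole horizon.
#'
#' @param spec a `scenario_spec`.
#' @param inputs an `slt_inputs` bundle (see [generate_bundle()] /
#'   [read_bundle()]): list with `exposure`, `rr`, `pop`, `epi`, `costs`,
#'   `defs`.
#' @param mc optional [mc_config()].
#' @param horizon_years,discount_rate passed to [run_comparison()].
#' @return `slt_output` (deterministic) or `slt_mc_summary` (Monte-Carlo).
#' @export
run_scenario <- function(spec, inputs, mc = NULL, horizon_years = 1,
                         discount_rate = 0) {
  state <- build_model(inputs$pop, inputs$epi, inputs$costs,
                       inputs$defs %||% default_disease_definitions())
  if (is.null(mc)) {
    pifs <- scenario_pifs(spec, inputs$exposure, inputs$rr, state$defs)
    run_comparison(state, pifs, horizon_years, discount_rate)
  } else {
    run_monte_carlo(spec, inputs, mc, horizon_years, discount_rate)
  }
}

#' Coverage threshold analysis
#'
#' Finds the fraction of the moderate + high sitting population that must
#' reduce daily sitting by `minutes_reduced` for the HALY gain to hit
#' `target_halys`.  HALYs are monotone increasing in coverage, so bisection on
#' `[0, 1]` is valid; convergence requires
#' `|achieved - target| / target < 1e-3`.
#'
#' @param minutes_reduced minutes/day reduction given to covered persons.
#' @param target_halys positive HALY target.
#' @param inputs an `slt_inputs` bundle.
#' @param horizon_years,discount_rate passed through to the life table.
#' @param max_iter bisection iteration cap.
#' @return list of class `threshold_result`: `coverage, achieved_halys,
#'   iterations, converged`.
#' @export
threshold_coverage <- function(minutes_reduced, target_halys, inputs,
                               horizon_years = 1, discount_rate = 0,
                               max_iter = 60) {
  if (target_halys <= 0) abort_domain("target_halys must be > 0")
  state <- build_model(inputs$pop, inputs$epi, inputs$costs,
                       inputs$defs %||% default_disease_definitions())
  spec <- scenario_spec("threshold", "sitting_reduction",
                        minutes_reduced = minutes_reduced)
  halys_at <- function(cov) {
    pifs <- scenario_pifs(spec, inputs$exposure, inputs$rr, state$defs,
                          coverage = cov)
    run_comparison(state, pifs, horizon_years, discount_rate)$totals[["halys_gained"]]
  }
  h1 <- halys_at(1)
  if (target_halys > h1) {
    return(structure(list(coverage = 1, achieved_halys = h1, iterations = 1L,
                          converged = FALSE), class = "threshold_result"))
  }
  lo <- 0; hi <- 1
  achieved <- h1
  mid <- 1
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mid <- (lo + hi) / 2
    achieved <- halys_at(mid)
    if (abs(achieved - target_halys) / target_halys < 1e-3 || iter >= max_iter) break
    if (achieved < target_halys) lo <- mid else hi <- mid
  }
  structure(list(coverage = mid, achieved_halys = achieved, iterations = iter,
                 converged = abs(achieved - target_halys) / target_halys < 1e-3),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Coverage %.4f -> %.2f HALYs (%s after %d iterations)\n",
              x$coverage, x$achieved_halys,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}
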