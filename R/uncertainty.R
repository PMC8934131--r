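# Second-order (parameter) Monte-Carlo uncertainty.
#
# Per draw: relative risks are sampled from normals on the natural scale
# (truncated below at 1e-6; optionally lognormal via rr_scale = "log"),
# category mean sitting times from moment-matched lognormals, and category
# proportions from truncated normals renormalised to sum to 1.  The
# deterministic pipeline is re-run on the perturbed inputs and each output is
# summarised with its mean and percentile 95% uncertainty interval.  Draws are
# deterministic functions of (seed, draw index).

#' Monte-Carlo configuration
#'
#' @param draws number of iterations (model default 2000).
#' @param seed integer master seed (mandatory).
#' @param rr_scale `"natural"` (default) or `"log"` RR sampling scale.
#' @param proportion_sampling `"truncated_normal_renormalised"` (default) or
#'   `"fixed"`.
#' @param sample_costs also sample per-case costs from a gamma distribution
#'   with coefficient of variation `cost_cv` (default off; the underlying
#'   expenditure data carry no published uncertainty).
#' @param cost_cv coefficient of variation for cost sampling.
#' @return list of class `mc_config`.
#' @export
mc_config <- function(draws = 2000, seed, rr_scale = c("natural", "log"),
                      proportion_sampling = c("truncated_normal_renormalised", "fixed"),
                      sample_costs = FALSE, cost_cv = 0.2) {
  if (missing(seed)) abort_validation("mc_config requires an explicit seed")
  if (draws < 1) abort_domain("draws must be >= 1")
  structure(list(draws = as.integer(draws), seed = as.integer(seed),
                 rr_scale = match.arg(rr_scale),
                 proportion_sampling = match.arg(proportion_sampling),
                 sample_costs = sample_costs, cost_cv = cost_cv),
            class = "mc_config")
}

# truncated-at-zero normal draws (rejection sampling, bounded retries)
rtnorm0 <- function(n, mean, sd) {
  out <- rnorm(n, mean, sd)
  for (tries in 1:100) {
    bad <- out < 0
    if (!any(bad)) break
    out[bad] <- rnorm(sum(bad), mean[bad], sd[bad])
  }
  pmax(out, 0)
}

#' Sample one perturbed input bundle
#'
#' Deterministic in `(mc$seed, draw_index)`.  Inputs whose standard errors (or
#' CI widths) are zero are passed through unchanged, so a zero-uncertainty
#' bundle collapses every draw onto the base inputs exactly.
#'
#' @param inputs an `slt_inputs` bundle.
#' @param mc an [mc_config()].
#' @param draw_index draw number (1-based).
#' @return perturbed copy of `inputs`.
#' @export
sample_inputs <- function(inputs, mc, draw_index) {
  set.seed(draw_seed(mc$seed, draw_index))
  out <- inputs
  # relative risks (non-reference rows only)
  rr <- inputs$rr
  idx <- which(rr$category != "low")
  for (k in idx) {
    pr <- rr_sampling_params(rr$rr[k], rr$ci_low[k], rr$ci_high[k], mc$rr_scale)
    if (pr[["spread"]] == 0) next
    rr$rr[k] <- if (mc$rr_scale == "natural") {
      max(rnorm(1, pr[["location"]], pr[["spread"]]), 1e-6)
    } else {
      exp(rnorm(1, pr[["location"]], pr[["spread"]]))
    }
  }
  out$rr <- rr
  # exposure: category means (lognormal) and proportions (truncated normal)
  exp_tab <- inputs$exposure
  key <- paste(exp_tab$sex, exp_tab$age_band)
  for (k in unique(key)) {
    sidx <- which(key == k)
    sl <- exp_tab[sidx, ]
    ord <- match(SB_LEVELS, sl$category)
    exp_tab$mean_minutes[sidx[ord]] <-
      sample_means(sl$mean_minutes[ord], sl$mean_se[ord])
    if (mc$proportion_sampling == "truncated_normal_renormalised" &&
        any(sl$proportion_se > 0)) {
      p <- rtnorm0(3, sl$proportion[ord], sl$proportion_se[ord])
      if (sum(p) <= 0) p <- sl$proportion[ord]
      exp_tab$proportion[sidx[ord]] <- p / sum(p)
    }
  }
  out$exposure <- exp_tab
  if (isTRUE(mc$sample_costs)) {
    costs <- inputs$costs
    pos <- costs$cost_aud > 0
    shape <- 1 / mc$cost_cv^2
    costs$cost_aud[pos] <- rgamma(sum(pos), shape = shape,
                                  rate = shape / costs$cost_aud[pos])
    out$costs <- costs
  }
  out
}

#' Run a scenario under Monte-Carlo parameter uncertainty
#'
#' Re-runs the deterministic pipeline once per draw on sampled inputs and
#' summarises every output metric (totals, per sex, per sex x disease) with
#' its empirical mean and 2.5/97.5 percentile uncertainty interval.  A fixed
#' seed gives bit-identical summaries across runs; summaries are invariant to
#' draw reordering.
#'
#' @param spec a `scenario_spec`.
#' @param inputs an `slt_inputs` bundle.
#' @param mc an [mc_config()].
#' @param horizon_years,discount_rate passed to [run_comparison()].
#' @param keep_draws retain the per-draw metric matrix as attribute `"draws"`.
#' @return object of class `slt_mc_summary`: data.frame `metric, mean,
#'   ui_low, ui_high` with attribute `draws_used`.
#' @export
run_monte_carlo <- function(spec, inputs, mc, horizon_years = 1,
                            discount_rate = 0, keep_draws = FALSE) {
  defs <- inputs$defs %||% default_disease_definitions()
  state <- build_model(inputs$pop, inputs$epi, inputs$costs, defs)
  flatten <- function(out) {
    v <- out$totals
    names(v) <- paste0("total.", names(v))
    bs <- out$by
    if (nrow(bs)) {
      m <- as.matrix(bs[c("halys_gained", "cost_offset", "deaths_averted",
                          "incident_cases_prevented")])
      v2 <- as.numeric(t(m))
      names(v2) <- as.vector(t(outer(paste(bs$sex, bs$disease, sep = "."),
                                     colnames(m),
                                     function(a, b) paste(b, a, sep = "."))))
      v <- c(v, v2)
    }
    v
  }
  draws_mat <- NULL
  for (j in seq_len(mc$draws)) {
    inp_j <- sample_inputs(inputs, mc, j)
    st_j <- if (isTRUE(mc$sample_costs)) {
      build_model(inp_j$pop, inp_j$epi, inp_j$costs, defs)
    } else state
    pifs_j <- scenario_pifs(spec, inp_j$exposure, inp_j$rr, defs)
    out_j <- flatten(run_comparison(st_j, pifs_j, horizon_years, discount_rate))
    if (is.null(draws_mat)) {
      draws_mat <- matrix(NA_real_, mc$draws, length(out_j),
                          dimnames = list(NULL, names(out_j)))
    }
    draws_mat[j, ] <- out_j
  }
  summ <- data.frame(
    metric = colnames(draws_mat),
    mean = colMeans(draws_mat),
    ui_low = apply(draws_mat, 2, quantile, probs = 0.025, names = FALSE),
    ui_high = apply(draws_mat, 2, quantile, probs = 0.975, names = FALSE),
    row.names = NULL
  )
  attr(summ, "draws_used") <- mc$draws
  if (keep_draws) attr(summ, "draws") <- draws_mat
  class(summ) <- c("slt_mc_summary", "data.frame")
  summ
}

#' @export
print.slt_mc_summary <- function(x, ...) {
  cat(sprintf("Monte-Carlo summary (%d draws)\n", attr(x, "draws_used")))
  tot <- x[startsWith(x$metric, "total."), ]
  for (k in seq_len(nrow(tot))) {
    cat(sprintf("  %-30s %12.1f (95%% UI %.1f to %.1f)\n",
                sub("^total\\.", "", tot$metric[k]),
                tot$mean[k], tot$ui_low[k], tot$ui_high[k]))
  }
  invisible(x)
}
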