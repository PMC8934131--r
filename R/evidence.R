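# Evidence synthesis: random-effects REML pooling of study relative risks,
# heterogeneity, and conversion of RR confidence intervals to sampling
# distributions.  Risk ratios and hazard ratios are treated interchangeably.

# log-scale effect and its standard error from an RR with a 95% CI
log_effects <- function(effects) {
  require_columns(effects, c("rr", "ci_low", "ci_high"), "study effects")
  if (any(effects$rr <= 0 | effects$ci_low <= 0 | effects$ci_high <= 0)) {
    abort_validation("relative risks and CI bounds must be > 0")
  }
  if (any(effects$ci_low > effects$rr | effects$rr > effects$ci_high)) {
    abort_validation("each study must satisfy ci_low <= rr <= ci_high")
  }
  y <- log(effects$rr)
  se <- (log(effects$ci_high) - log(effects$ci_low)) / (2 * Z95)
  list(y = y, se = se)
}

# restricted log-likelihood of a random-effects location model at tau2
reml_loglik <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
}

# REML estimate of the between-study variance on the log scale
reml_tau2 <- function(y, v) {
  if (length(y) < 2) return(0)
  ub <- max(10 * stats::var(y), 1e-3)
  opt <- stats::optimize(reml_loglik, c(0, ub), y = y, v = v,
                         maximum = TRUE, tol = 1e-12)
  # the optimum may sit on the boundary; prefer 0 when it is not worse
  if (reml_loglik(0, y, v) >= opt$objective) 0 else max(opt$maximum, 0)
}

#' Pool study relative risks with a random-effects REML model
#'
#' Pools study-level relative risks (or hazard ratios) on the log scale.  The
#' between-study variance `tau2` maximises the restricted log-likelihood; the
#' pooled effect is the inverse-variance weighted mean with weights
#' `1 / (se^2 + tau2)` and a plain normal-approximation 95% CI (no
#' Knapp-Hartung adjustment).  A single study is returned unchanged with
#' `tau2 = 0`.
#'
#' @param effects data.frame with columns `rr, ci_low, ci_high` (optionally
#'   `study_id, disease, contrast`); all rows must share disease and contrast.
#' @return object of class `pooled_rr`: a list with `rr, ci_low, ci_high,
#'   log_rr, se, tau2, i2, k` (plus `disease`/`contrast` when present).
#' @export
pool_random_effects_reml <- function(effects) {
  if (is.null(effects) || nrow(effects) == 0) {
    abort_validation("cannot pool an empty set of study effects")
  }
  for (col in c("disease", "contrast")) {
    if (col %in% names(effects) && length(unique(effects[[col]])) > 1) {
      abort_validation(sprintf("all pooled studies must share the same %s", col))
    }
  }
  le <- log_effects(effects)
  if (any(le$se <= 0)) abort_validation("study log-RR standard errors must be > 0")
  k <- length(le$y)
  if (k == 1) {
    # a single study is returned verbatim (its CI may be asymmetric)
    return(structure(list(
      disease = if ("disease" %in% names(effects)) effects$disease[1] else NA_character_,
      contrast = if ("contrast" %in% names(effects)) effects$contrast[1] else NA_character_,
      rr = effects$rr[1], ci_low = effects$ci_low[1], ci_high = effects$ci_high[1],
      log_rr = le$y, se = le$se, tau2 = 0, i2 = NA_real_, k = 1L
    ), class = "pooled_rr"))
  }
  tau2 <- reml_tau2(le$y, le$se^2)
  w <- 1 / (le$se^2 + tau2)
  mu <- sum(w * le$y) / sum(w)
  se_mu <- sqrt(1 / sum(w))
  structure(list(
    disease = if ("disease" %in% names(effects)) effects$disease[1] else NA_character_,
    contrast = if ("contrast" %in% names(effects)) effects$contrast[1] else NA_character_,
    rr = exp(mu),
    ci_low = exp(mu - Z95 * se_mu),
    ci_high = exp(mu + Z95 * se_mu),
    log_rr = mu, se = se_mu,
    tau2 = tau2,
    i2 = if (k >= 2) i_squared(effects) else NA_real_,
    k = k
  ), class = "pooled_rr")
}

#' @export
print.pooled_rr <- function(x, ...) {
  cat(sprintf("Pooled RR %.3f (95%% CI %.3f-%.3f), k = %d, tau^2 = %.5f, I^2 = %s\n",
              x$rr, x$ci_low, x$ci_high, x$k, x$tau2,
              if (is.na(x$i2)) "NA" else sprintf("%.1f%%", 100 * x$i2)))
  invisible(x)
}

#' I-squared heterogeneity statistic
#'
#' `I^2 = max(0, (Q - (k - 1)) / Q)` where Q is Cochran's Q under
#' fixed-effect inverse-variance weights on the log-RR scale.  `Q = 0`
#' (identical studies) gives 0.
#'
#' @param effects data.frame of at least two studies (`rr, ci_low, ci_high`).
#' @return fraction in `[0, 1]`.
#' @export
i_squared <- function(effects) {
  if (nrow(effects) < 2) abort_validation("I^2 requires at least two studies")
  le <- log_effects(effects)
  w <- 1 / le$se^2
  mu_fe <- sum(w * le$y) / sum(w)
  Q <- sum(w * (le$y - mu_fe)^2)
  if (Q <= 0) 0 else max(0, (Q - (length(le$y) - 1)) / Q)
}

#' Sampling parameters for a relative risk given its 95% CI
#'
#' On the natural scale (the model default) the RR is sampled from a normal
#' distribution with `location = rr` and `spread = (ci_high - ci_low) /
#' (2 * 1.959964)`; draws are later truncated below at `1e-6` so risks stay
#' positive.  On the log scale the same construction is applied to the logged
#' quantities (a lognormal RR).
#'
#' @param rr,ci_low,ci_high point estimate and 95% CI, `0 < ci_low <= rr <= ci_high`.
#' @param scale `"natural"` (default) or `"log"`.
#' @return named numeric `c(location, spread)`.
#' @export
rr_sampling_params <- function(rr, ci_low, ci_high, scale = c("natural", "log")) {
  scale <- match.arg(scale)
  if (!(ci_low > 0 && ci_low <= rr && rr <= ci_high)) {
    abort_validation("need 0 < ci_low <= rr <= ci_high")
  }
  if (scale == "natural") {
    c(location = rr, spread = (ci_high - ci_low) / (2 * Z95))
  } else {
    c(location = log(rr), spread = (log(ci_high) - log(ci_low)) / (2 * Z95))
  }
}

# internal: validate an RR table (long format incl. low reference rows)
validate_rr_table <- function(df) {
  require_columns(df, c("disease", "category", "rr", "ci_low", "ci_high"),
                  "relative-risk table")
  df$disease <- as.character(df$disease)
  df$category <- as.character(df$category)
  if (any(df$rr <= 0)) abort_validation("all relative risks must be > 0")
  for (d in unique(df$disease)) {
    have <- df$category[df$disease == d]
    if (!all(c("low", "moderate", "high") %in% have)) {
      abort_validation(sprintf(
        "disease %s must have rows for low, moderate and high categories", d))
    }
  }
  lowr <- df[df$category == "low", ]
  if (any(lowr$rr != 1 | lowr$ci_low != 1 | lowr$ci_high != 1)) {
    abort_validation("reference (low) category must have rr = 1 with a zero-width CI")
  }
  df <- df[order(df$disease, match(df$category, SB_LEVELS)), ]
  rownames(df) <- NULL
  class(df) <- c("rr_table", "data.frame")
  df
}

#' Load a disease x category relative-risk table from CSV
#'
#' Expects columns `disease, category, rr, ci_low, ci_high` with categories
#' `moderate` and `high` (contrast vs the low-sitting reference); reference
#' rows `rr = 1 (1; 1)` are added automatically if absent.
#'
#' The packaged fixture of pooled meta-analysis RRs is at
#' `system.file("extdata", "table3_rr.csv", package = "sedlift")`.
#'
#' @param path CSV file path.
#' @return an `rr_table` (data.frame subclass).
#' @export
load_rr_table <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("RR file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("disease", "category", "rr", "ci_low", "ci_high"),
                  "relative-risk table")
  if (!"low" %in% df$category) {
    ref <- data.frame(disease = unique(df$disease), category = "low",
                      rr = 1, ci_low = 1, ci_high = 1)
    df <- merge(df, ref, all = TRUE)
  }
  validate_rr_table(df[c("disease", "category", "rr", "ci_low", "ci_high")])
}

#' Built-in pooled relative-risk fixture
#' @return the packaged `rr_table`.
#' @export
default_rr_table <- function() {
  load_rr_table(system.file("extdata", "table3_rr.csv", package = "sedlift"))
}

# named RR vector c(low, moderate, high) for one disease
rr_vector <- function(rr_table, disease) {
  sl <- rr_table[rr_table$disease == disease, ]
  if (nrow(sl) != 3) abort_validation(sprintf("disease %s not in RR table", disease))
  setNames(sl$rr[match(SB_LEVELS, sl$category)], SB_LEVELS)
}
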