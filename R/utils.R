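# shared constants, error classes and small helpers

# 97.5% normal quantile used to convert 95% CIs to standard errors
Z95 <- stats::qnorm(0.975)

SEXES <- c("female", "male")
SB_LEVELS <- c("low", "moderate", "high")
AGE_BANDS <- c("18-24", "25-34", "35-44", "45-54", "55-64", "65-74", "75+")

# CLI contract: validation errors exit 2, numerical/other failures exit 3
abort_validation <- function(msg) {
  stop(structure(
    class = c("slt_validation_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

abort_domain <- function(msg) {
  stop(structure(
    class = c("slt_domain_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Age band containing an age
#'
#' Maps single-year ages onto the seven exposure age bands
#' (18-24, 25-34, ..., 75+).
#'
#' @param age integer vector of ages in years (>= 18).
#' @return character vector of band labels.
#' @export
age_band_of <- function(age) {
  if (any(age < 18)) abort_domain("ages below 18 are outside the model population")
  as.character(cut(age, breaks = c(18, 25, 35, 45, 55, 65, 75, Inf),
                   labels = AGE_BANDS, right = FALSE))
}

# single-year ages covered by a band label, clipped to [min_age, max_age]
ages_in_band <- function(band, min_age = 18L, max_age = 100L) {
  rng <- switch(band,
    "18-24" = c(18L, 24L), "25-34" = c(25L, 34L), "35-44" = c(35L, 44L),
    "45-54" = c(45L, 54L), "55-64" = c(55L, 64L), "65-74" = c(65L, 74L),
    "75+" = c(75L, max_age),
    abort_validation(sprintf("unknown age band '%s'", band)))
  lo <- max(rng[1], min_age)
  hi <- min(rng[2], max_age)
  if (lo > hi) integer(0) else seq.int(lo, hi)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_validation(sprintf("%s is missing column(s): %s",
                             what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# derive a per-draw RNG seed from a top-level seed; kept below 2^31
draw_seed <- function(seed, draw_index) {
  as.integer((as.numeric(seed) %% 65521) * 32749 + as.numeric(draw_index) %% 32749)
}
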