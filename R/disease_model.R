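# Four-state generic disease engine: healthy (S), diseased (C),
# dead-from-disease (Dd), dead-other-causes (Do).  Transitions: S->C at
# incidence i, C->S at remission r, C->Dd at case fatality f, S,C->Do at the
# background (all-cause) mortality rate.  Rates are piecewise constant on
# one-year age intervals; each interval is solved exactly.

#' Default definitions of the five modelled diseases
#'
#' Breast and endometrial cancer are modelled in females only.  Cost basis
#' follows the national expenditure data: colorectal and endometrial cancer
#' carry a cost per incident case, breast cancer, type 2 diabetes and stroke a
#' cost per prevalent case.  Remission is 0 by default for all five.
#'
#' @return data.frame `name, sexes, cost_basis, remission_allowed`.
#' @export
default_disease_definitions <- function() {
  data.frame(
    name = c("type2_diabetes", "stroke", "breast_cancer",
             "colorectal_cancer", "endometrial_cancer"),
    sexes = c("both", "both", "female", "both", "female"),
    cost_basis = c("per_prevalent_case", "per_prevalent_case",
                   "per_prevalent_case", "per_incident_case",
                   "per_incident_case"),
    remission_allowed = FALSE
  )
}

# sexes a disease applies to, as a character vector
disease_sexes <- function(defs, disease) {
  s <- defs$sexes[defs$name == disease]
  if (!length(s)) abort_validation(sprintf("unknown disease '%s'", disease))
  if (s == "both") SEXES else s
}

# stable (1 - exp(-x t)) / x, with the x -> 0 limit t
.fexp <- function(x, t) {
  out <- ifelse(abs(x * t) < 1e-8, t * (1 - x * t / 2), -expm1(-x * t) / x)
  out
}

# One exact constant-rate step of the remission-free two-compartment system.
# Vectorised over cohorts.  Returns end-of-interval states and the integrals
# of S and C over the interval (person-time), from which the person-time-
# weighted average prevalence Ic / (Is + Ic) follows.
id_step_closed <- function(s0, c0, i, f, mu, dt = 1) {
  a <- i + mu          # outflow from healthy
  b <- f + mu          # outflow from diseased
  ea <- exp(-a * dt)
  eb <- exp(-b * dt)
  Fa <- .fexp(a, dt)
  Fb <- .fexp(b, dt)
  d <- b - a
  near <- abs(d) < 1e-9
  g_end <- ifelse(near, dt * ea, (ea - eb) / d)
  g_int_lim <- ifelse(abs(a * dt) < 1e-6, dt^2 / 2,
                      (1 - (1 + a * dt) * exp(-a * dt)) / a^2)
  g_int <- ifelse(near, g_int_lim, (Fa - Fb) / d)
  s1 <- s0 * ea
  c1 <- c0 * eb + i * s0 * g_end
  Is <- s0 * Fa
  Ic <- c0 * Fb + i * s0 * g_int
  list(s1 = s1, c1 = c1, Is = Is, Ic = Ic,
       dDd = f * Ic, dDo = mu * (Is + Ic))
}

# general step via the matrix exponential of the 4x4 generator (handles r > 0);
# augmented 8x8 exponential yields the state integrals in the same call
id_step_expm <- function(x0, i, f, r, mu, dt = 1) {
  Q <- rbind(c(-(i + mu), i, 0, mu),
             c(r, -(r + f + mu), f, mu),
             c(0, 0, 0, 0),
             c(0, 0, 0, 0))
  M <- rbind(cbind(Q, diag(4)), matrix(0, 4, 8))
  E <- as.matrix(Matrix::expm(M * dt))
  x1 <- as.numeric(x0 %*% E[1:4, 1:4])
  xi <- as.numeric(x0 %*% E[1:4, 5:8])
  list(x1 = x1, xint = xi)
}

#' Solve the illness-death model over an age range
#'
#' Integrates the four-state system with piecewise-constant rates per one-year
#' age interval, using the exact constant-rate solution (closed form when
#' remission is zero, matrix exponential otherwise).  Prevalence among the
#' living is `p = C / (S + C)` and disease-attributable mortality
#' `m_d = p * f`.
#'
#' @param i,f,r,m_other incidence, case fatality, remission and
#'   other-cause mortality rates (per person-year); vectors over the ages
#'   `start_age:end_age` (the value at `end_age` is only used to report
#'   `m_d` at that age).
#' @param start_age,end_age integer ages in years, `end_age > start_age`.
#' @param init length-4 initial state `(S, C, Dd, Do)` summing to 1;
#'   default is fully healthy.
#' @return data.frame `age, S, C, Dd, Do, p, m_d` with one row per age; the
#'   attribute `"p_bar"` holds the person-time-weighted average prevalence on
#'   each interval (length `end_age - start_age`).
#' @export
solve_illness_death <- function(i, f, r = 0, m_other = 0, start_age, end_age,
                                init = c(1, 0, 0, 0)) {
  ages <- seq.int(start_age, end_age)
  n <- length(ages)
  rec <- function(x, nm) {
    x <- rep_len(x, n)
    if (any(x < 0)) abort_validation(sprintf("%s rates must be >= 0", nm))
    x
  }
  i <- rec(i, "incidence"); f <- rec(f, "case fatality")
  r <- rec(r, "remission"); m_other <- rec(m_other, "other-cause mortality")
  if (abs(sum(init) - 1) > 1e-9 || any(init < 0)) {
    abort_validation("init must be a non-negative state vector summing to 1")
  }
  S <- C <- Dd <- Do <- numeric(n)
  p_bar <- numeric(n - 1)
  S[1] <- init[1]; C[1] <- init[2]; Dd[1] <- init[3]; Do[1] <- init[4]
  for (t in seq_len(n - 1)) {
    if (r[t] == 0) {
      st <- id_step_closed(S[t], C[t], i[t], f[t], m_other[t])
      S[t + 1] <- st$s1; C[t + 1] <- st$c1
      Dd[t + 1] <- Dd[t] + st$dDd; Do[t + 1] <- Do[t] + st$dDo
      p_bar[t] <- st$Ic / (st$Is + st$Ic)
    } else {
      st <- id_step_expm(c(S[t], C[t], Dd[t], Do[t]), i[t], f[t], r[t], m_other[t])
      S[t + 1] <- st$x1[1]; C[t + 1] <- st$x1[2]
      Dd[t + 1] <- st$x1[3]; Do[t + 1] <- st$x1[4]
      p_bar[t] <- st$xint[2] / (st$xint[1] + st$xint[2])
    }
  }
  p <- C / (S + C)
  out <- data.frame(age = ages, S = S, C = C, Dd = Dd, Do = Do,
                    p = p, m_d = p * f)
  attr(out, "p_bar") <- p_bar
  out
}

#' Scale disease incidence by a potential impact fraction
#'
#' Applies `i'(a) = i(a) * (1 - pif)` to the ages inside each PIF row's age
#' band (and matching sex).  Prevalence and disease mortality are *not*
#' touched here; they are re-derived downstream so the scenario and baseline
#' differ only through incidence.
#'
#' @param epi disease epidemiology data.frame (`disease, sex, age, incidence,
#'   prevalence, case_fatality, remission, yld_rate, disability_weight`).
#' @param pif data.frame `sex, age_band, pif` (optionally `disease`, which
#'   must then match).
#' @return the epi data.frame with adjusted incidence.
#' @export
adjust_incidence <- function(epi, pif) {
  if (any(pif$pif > 1)) abort_validation("PIF values must be <= 1")
  if ("disease" %in% names(pif) && length(unique(epi$disease)) == 1) {
    pif <- pif[is.na(pif$disease) | pif$disease == epi$disease[1], ]
  }
  max_age <- max(epi$age)
  for (k in seq_len(nrow(pif))) {
    ages <- ages_in_band(pif$age_band[k], min_age = min(epi$age), max_age = max_age)
    idx <- epi$sex == pif$sex[k] & epi$age %in% ages
    epi$incidence[idx] <- epi$incidence[idx] * (1 - pif$pif[k])
  }
  epi
}

#' Re-derive prevalence and disease mortality from incidence and case fatality
#'
#' Runs the illness-death solver forward over the age range, per sex, starting
#' from the supplied prevalence at the first age, and replaces `prevalence`
#' and `yld_rate` (`= p * disability_weight`) with the internally consistent
#' trajectory.  Applying this to a bundle whose prevalence was generated by
#' the same solver reproduces it exactly (idempotence).
#'
#' @param epi disease epidemiology data.frame for one disease.
#' @param m_other_fn function `(sex) -> vector` of other-cause mortality rates
#'   over the epi age range (typically the all-cause rates of the population
#'   table); defaults to zero.
#' @return epi with consistent `prevalence` and `yld_rate`.
#' @export
derive_prevalence_and_mortality <- function(epi, m_other_fn = function(sex) 0) {
  for (sex in unique(epi$sex)) {
    idx <- which(epi$sex == sex)
    sl <- epi[idx, ]
    sl <- sl[order(sl$age), ]
    p0 <- sl$prevalence[1]
    sol <- solve_illness_death(sl$incidence, sl$case_fatality, sl$remission,
                               m_other_fn(sex),
                               start_age = min(sl$age), end_age = max(sl$age),
                               init = c(1 - p0, p0, 0, 0))
    epi$prevalence[idx[order(epi$age[idx])]] <- sol$p
    epi$yld_rate[idx[order(epi$age[idx])]] <-
      sol$p * sl$disability_weight
  }
  epi
}

#' Load disease epidemiology tables from CSV
#'
#' Schema: `disease, sex, age, incidence, prevalence, case_fatality,
#' remission, yld_rate, disability_weight`, one row per disease x sex x age.
#'
#' @param path CSV file path.
#' @return named list of per-disease data.frames.
#' @export
load_disease_epi <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("epi file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("disease", "sex", "age", "incidence", "prevalence",
                        "case_fatality", "remission", "yld_rate",
                        "disability_weight"), "disease epi table")
  if (any(df$incidence < 0 | df$case_fatality < 0 | df$remission < 0)) {
    abort_validation("epi rates must be >= 0")
  }
  if (any(df$prevalence < 0 | df$prevalence >= 1)) {
    abort_validation("prevalence must lie in [0, 1)")
  }
  split(df, df$disease)
}
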