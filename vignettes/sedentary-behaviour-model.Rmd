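---
title: "Modelling the health and economic impact of reducing population sitting time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the health and economic impact of reducing population sitting time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model in brief

Prolonged daily sitting (sedentary behaviour) is an independent risk factor
for several chronic diseases.  `sedlift` estimates what a population-level
reduction in sitting time would be worth in health and healthcare spending.
It chains four components:

1. **Exposure.**  Adults are classified into three daily-sitting categories —
   low (< 4 h), moderate (4–8 h) and high (> 8 h) — with, per sex and
   age band, the proportion of the population in each category and the mean
   sitting minutes within it.  Category bounds are half-open
   `[lower, upper)`: 240 min is moderate and 480 min is high.  The published
   survey table behind the packaged fixture writes "4–8 h" and "> 8 h"
   without resolving the boundary; half-open binning is chosen purely for
   determinism.

2. **Potential impact fractions.**  A change in the exposure distribution is
   converted to a proportional change in disease incidence with the
   categorical PIF
   $$\mathrm{PIF} \;=\; \frac{\sum_c p_c\,RR_c - \sum_c p^{cf}_c\,RR^{cf}_c}
                             {\sum_c p_c\,RR_c},$$
   where $p_c$ are baseline category proportions, $RR_c$ category relative
   risks (low = 1) and the $^{cf}$ quantities describe the counterfactual.
   Scenarios that move *people between categories* change $p^{cf}$
   (prevalence shift).  Scenarios that shave minutes off sitting *within*
   categories keep $p$ fixed and move the category RRs down a piecewise
   log-linear dose–response anchored at the category means
   (relative-risk shift): the slope of the moderate segment is
   $\log(RR_m)/(\bar{x}_m-\bar{x}_l)$ and of the high segment
   $(\log RR_h - \log RR_m)/(\bar{x}_h-\bar{x}_m)$, and shifted RRs are
   floored at 1 so the dose–response is never extrapolated below the
   reference.  The dose–response form is not printed in the source
   literature; piecewise log-linearity through the three anchor points is the
   natural interpolant for categorical relative risks and its endpoint
   consistency (a full traversal of a segment lands exactly on the adjacent
   category's RR) is enforced by test.

3. **Disease processes.**  Each disease runs a four-state illness–death
   process — healthy, diseased, dead from the disease, dead from other
   causes — with incidence $i$, remission $r$ (0 by default for all five
   diseases: diabetes and post-acute stroke are treated as chronic, the
   cancers as prevalent conditions), case fatality $f$ and background
   mortality.  Rates are piecewise constant on one-year age intervals and
   each interval is solved **exactly**: a closed form when $r = 0$, the
   matrix exponential of the 4×4 generator otherwise.  A fine-grid Euler
   integrator exists only as a test oracle, never as a production path.
   Prevalence among the living is $p = C/(S+C)$ and disease-attributable
   mortality $m_d = p f$.

4. **Proportional multi-state life table.**  Every current-age cohort is
   projected forward in annual cycles under a business-as-usual arm and a
   scenario arm that differs *only* through incidence,
   $i'(a) = i(a)(1-\mathrm{PIF})$.  Prevalence differences feed back into the
   shared columns as
   $m'(x) = m(x) - \sum_d f_d\,(\bar p_d - \bar p'_d)$ and
   $w'(x) = w(x) - \sum_d dw_d\,(\bar p_d - \bar p'_d)$, and the life table
   uses $q = 1-e^{-m}$, survivors $l$, life years $L = (l + l_{+1})/2$ and
   health-adjusted life years $Lw = L(1-w)$.  HALYs gained are the discounted
   sum of $Lw' - Lw$ over the horizon; deaths averted and incident cases
   prevented are undiscounted counts; cost offsets price prevalent
   person-years (breast cancer, diabetes, stroke) or incident cases
   (colorectal and endometrial cancer) at the per-case cost.

Breast and endometrial cancer are modelled in females only, which is the
mechanical reason female HALY gains exceed male gains on otherwise symmetric
inputs — a property asserted in the acceptance suite on a deliberately
symmetric synthetic bundle, where it is literally forced.

## Numerical conventions that matter

* **Within-year prevalence.**  The mortality and morbidity feedbacks use the
  person-time-weighted average prevalence $\bar p$ over each annual interval,
  computed from the exact integrals of the constant-rate solution (stable
  `expm1`-based forms, with series limits where outflow rates coincide).
  Using start-of-year prevalence instead would make a one-year horizon
  degenerate: both arms start each cohort from identical prevalence, so every
  output would be exactly zero.
* **Horizon semantics.**  The published analysis accrues outcomes "over one
  year" while reporting HALY magnitudes suggestive of longer accrual; the
  ambiguity is left explicit rather than resolved.  `horizon_years`
  (default 1) and `discount_rate` (default 0; the source names no discount
  rate) are plain parameters, and a lifetime analysis is simply a long
  horizon.  Deaths averted are counted within the horizon window for the
  same reason — the window *is* the horizon.
* **Rate-to-probability conversion** is $q = 1 - e^{-m}$ (constant hazard
  within the year).
* **Exact attribution.**  Per-disease breakdowns must sum to totals to make
  the output auditable.  Each year's HALY gain splits into a mortality
  component $(L'-L)(1-w')$, attributed across diseases in proportion to
  their share of the mortality-rate reduction, and a morbidity component
  $L\,(w-w')$, attributed by each disease's own $\Delta p \cdot dw$ term.
  The shares sum to one by construction, so conservation holds to machine
  precision rather than approximately.
* **Proportionality.**  Diseases are independent within the life table (the
  standard proportional multi-state assumption); co-morbidity interaction is
  out of scope.  The background rate inside each disease process is the
  all-cause mortality rate without subtracting disease-specific mortality —
  a second-order approximation used consistently by the generator, the
  consistency engine and the life table, which is what makes the
  "generated prevalence equals the solver's output" property exact.

## Evidence synthesis

Study relative risks (risk and hazard ratios treated as interchangeable) are
pooled on the log scale with a random-effects model.  The between-study
variance $\tau^2$ maximises the restricted likelihood
$$\ell_R(\tau^2) = -\tfrac12\Big[\sum_k \log(v_k+\tau^2)
  + \log\sum_k w_k + \sum_k w_k (y_k-\hat\mu)^2\Big],
  \qquad w_k = (v_k+\tau^2)^{-1},$$
and the pooled effect is the $w_k$-weighted mean with a plain normal 95% CI —
no Knapp–Hartung adjustment, matching the way the pooled table was reported.
Heterogeneity is $I^2 = \max(0, (Q-(k-1))/Q)$.  Statistically non-significant
moderate-category RRs are retained as model inputs, again following the
source analysis.  The implementation is validated against an exhaustive
grid-search oracle and a 500-replicate parameter-recovery experiment; the
published pooled values themselves ship as a fixture because the underlying
study list is not available to re-derive them.

For uncertainty propagation the RRs are sampled from a **normal on the
natural scale** centred at the point estimate with spread
$(\mathrm{CI}_{hi}-\mathrm{CI}_{lo})/(2\times1.959964)$, truncated below at
$10^{-6}$.  This follows the source model even though several published CIs
are asymmetric; lognormal (log-scale) sampling is available as
`rr_scale = "log"` and the choice is logged.  Sitting-time means are sampled
from lognormals matched by moments, $\sigma^2=\log(1+(\mathrm{se}/\mu)^2)$,
$\mu_{\log}=\log\mu-\sigma^2/2$ (the fitting rule is not stated in the
source; moment matching is the standard choice).  Category proportions are
sampled as independent truncated normals and renormalised — the survey
publishes marginal SEs but no joint distribution.  All sampled parameters
are independent, and every draw is a pure function of `(seed, draw_index)`,
so results are reproducible regardless of execution order.  Whether the
source also sampled epidemiological rates and costs is unstated; by default
they are fixed, with optional gamma sampling of costs behind
`mc_config(sample_costs = TRUE)`.

## Scenarios and the coverage threshold

The four built-in scenarios: (1) everyone in the moderate and high categories
moves to low; (2) 30% of the high category moves to moderate; (3) 30% of the
moderate category moves to low; (4) sitting falls by 36.3 min/day in both the
moderate and high categories — the effect observed in a 12-month workplace
trial — implemented as a relative-risk shift on *both* category RRs (whether
the source shifted both or re-binned individuals is unstated; both-category
shifting is the default and the prevalence-based alternative can be composed
from the public operations).  Movers in a prevalence shift adopt the
destination category's existing mean, so category means never change; the
alternative "cap" convention (movers sit at the destination boundary) is
exposed through `scenario_average_reduction()` and the CLI's
`--target-convention` flag, but it only affects the descriptive
average-reduction statistic — prevalence-shift PIFs never touch the means,
so neither convention is asserted as the published intent.

Coverage — the fraction of the target population actually reached — enters as
a population mixture, `coverage × shifted + (1 − coverage) × baseline`.
Because the categorical PIF is linear in that mixture, coverage is an exact
linear multiplier on every stratum PIF, and HALYs are strictly increasing in
it; `threshold_coverage()` therefore inverts the forward model by bisection
to 0.1% relative tolerance.

## What the synthetic generator does and does not establish

The real inputs — survey microdata behind the sitting-time table, the
global-burden-of-disease epidemiology extraction, and national expenditure
tables — are not redistributable.  `generate_bundle()` emulates their
structure: ~19.5 million adults on ages 18–100 with Gompertz all-cause
mortality ($m(x)=2.7\times10^{-5}e^{0.09x}$, giving $m(40)\approx10^{-3}$
and $m(80)\approx0.04$), background morbidity rising linearly from 0.05 to
0.15, unimodal age-specific incidence per disease with case fatalities,
disability weights and per-case costs at burden-of-disease-plausible
magnitudes, and Dirichlet-distributed category proportions around
survey-like centres (30/36/34%).  Prevalence is always derived forward
through the illness–death engine, never drawn independently, so the internal
consistency the real inputs satisfy only approximately holds here exactly —
deliberately, because it turns consistency into a machine-precision test.
Default magnitudes put scenario outputs at $O(10^3)$ HALYs, the same order as
the published national model, but no generated number is claimed to match
the published tables: green tests establish that the *machinery* is correct
(oracle equivalence, conservation, monotonicity, dominance, reproducibility),
not that any headline figure is reproduced.  The published totals would
require the restricted inputs the generator only imitates.

The generator also does not emulate survey weights, record structures, or
between-age correlation in rates beyond smoothness — features a real
extraction would carry.

## Degenerate inputs and edge behaviour

Zero PIFs return exactly zero outputs (both arms are bitwise identical
computations).  Zero disability weights reduce HALYs to discounted life
years; zero costs give a zero offset identically.  Sitting reductions floor
category means at the category lower bound; shifted RRs floor at 1; sampled
RRs truncate at $10^{-6}$; scenario mortality is clamped at 0 with the
per-disease attribution rescaled so conservation survives clamping.  A
single-study meta-analysis returns the study verbatim (its CI may be
asymmetric, which a log-symmetric reconstruction would destroy).

## Known limitations

Only the five diseases with published category-specific relative risks are
modelled, so benefits are understated relative to the full set of
sitting-associated conditions; disease progression (as opposed to onset) is
not captured; intervention costs and cost-effectiveness ratios are out of
scope; exposure age bands are broadcast to single-year ages without
smoothing; and the one-year-horizon accounting ambiguity inherited from the
source is documented rather than resolved.
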