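# Proportional multi-state cohort life table.
#
# Every current-age cohort is simulated forward in annual cycles under a
# business-as-usual (BAU) arm and a scenario arm that differs only through
# disease incidence (scaled by 1 - PIF).  Each disease's prevalence evolves by
# the exact illness-death solution; the person-time-weighted average
# prevalence over each year feeds the mortality and morbidity adjustments
#   m'(x) = m(x) - sum_d f_d * (p_d - p'_d)
#   w'(x) = w(x) - sum_d dw_d * (p_d - p'_d)
# and the life-table columns q = 1 - exp(-m), l, L = (l + l(+1))/2,
# Lw = L * (1 - w).  HALYs gained accumulate (Lw' - Lw) with exponential
# discounting over the horizon.

#' Load the population table from CSV
#'
#' Schema: `sex, age, population, all_cause_mortality, total_yld_rate`.
#'
#' @param path CSV file path.
#' @return validated population data.frame, ordered by sex and age.
#' @export
load_population <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("population file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("sex", "age", "population", "all_cause_mortality",
                        "total_yld_rate"), "population table")
  if (any(df$population < 0) || any(df$all_cause_mortality < 0)) {
    abort_validation("population counts and mortality rates must be >= 0")
  }
  if (any(df$total_yld_rate < 0 | df$total_yld_rate > 1)) {
    abort_validation("total_yld_rate must lie in [0, 1]")
  }
  df[order(match(df$sex, SEXES), df$age), ]
}

#' Load healthcare costs per case from CSV
#'
#' Schema: `disease, sex, age_band, cost_basis, cost_aud`; `sex` and
#' `age_band` may be `"all"`.  Costs are multiplied by `inflation_index` at
#' load (e.g. a Health Price Index ratio taking historical prices to 2019
#' values).
#'
#' @param path CSV file path.
#' @param inflation_index scalar multiplier applied to every cost (default 1).
#' @return cost data.frame.
#' @export
load_costs <- function(path, inflation_index = 1) {
  if (!file.exists(path)) abort_validation(sprintf("cost file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("disease", "sex", "age_band", "cost_basis", "cost_aud"),
                  "cost table")
  if (any(df$cost_aud < 0)) abort_validation("costs must be >= 0")
  if (!all(df$cost_basis %in% c("per_incident_case", "per_prevalent_case"))) {
    abort_validation("cost_basis must be per_incident_case or per_prevalent_case")
  }
  defs <- default_disease_definitions()
  for (d in intersect(df$disease, defs$name)) {
    want <- defs$cost_basis[defs$name == d]
    have <- unique(df$cost_basis[df$disease == d])
    if (!identical(have, want)) {
      abort_validation(sprintf("disease %s costs must be on basis %s (got %s)",
                               d, want, paste(have, collapse = ",")))
    }
  }
  df$cost_aud <- df$cost_aud * inflation_index
  df
}

# per-age cost vector for one disease and sex
cost_by_age <- function(costs, disease, sex, ages) {
  sl <- costs[costs$disease == disease &
                (costs$sex == sex | costs$sex == "all"), ]
  if (!nrow(sl)) abort_validation(sprintf("no cost rows for disease %s", disease))
  out <- numeric(length(ages))
  bands <- age_band_of(ages)
  for (k in seq_len(nrow(sl))) {
    if (sl$age_band[k] == "all") {
      out[] <- sl$cost_aud[k]
    } else {
      out[bands == sl$age_band[k]] <- sl$cost_aud[k]
    }
  }
  out
}

#' Assemble and validate the life-table model state
#'
#' @param pop population table (see [load_population()]); must cover both
#'   sexes on a common age grid.
#' @param diseases named list of disease epidemiology data.frames (one per
#'   disease, covering the population age grid for each applicable sex).
#' @param costs cost table (see [load_costs()]); required when `diseases` is
#'   non-empty.
#' @param defs disease definitions (default [default_disease_definitions()]).
#' @return immutable model state of class `slt_model`.
#' @export
build_model <- function(pop, diseases = list(), costs = NULL,
                        defs = default_disease_definitions()) {
  ages <- sort(unique(pop$age))
  for (sex in SEXES) {
    have <- sort(pop$age[pop$sex == sex])
    if (!identical(have, ages)) {
      abort_validation(sprintf("population table: sex %s does not cover ages %d-%d",
                               sex, min(ages), max(ages)))
    }
  }
  for (d in names(diseases)) {
    epi <- diseases[[d]]
    for (sex in disease_sexes(defs, d)) {
      have <- sort(epi$age[epi$sex == sex])
      if (!identical(have, ages)) {
        miss <- setdiff(ages, have)
        abort_validation(sprintf(
          "disease %s (%s): epi grid missing age(s) %s", d, sex,
          paste(utils::head(miss, 8), collapse = ", ")))
      }
    }
    if (is.null(costs) || !d %in% costs$disease) {
      abort_validation(sprintf("no cost rows supplied for disease %s", d))
    }
  }
  structure(list(pop = pop, epi = diseases, costs = costs, defs = defs,
                 ages = ages, sexes = SEXES),
            class = "slt_model")
}

#' Compare business-as-usual and scenario arms of the life table
#'
#' Runs every sex x current-age cohort forward `horizon_years` annual cycles
#' in both arms and accumulates, by sex and disease: HALYs gained, healthcare
#' cost offsets (A$, discounted), deaths averted and incident cases prevented
#' (undiscounted counts).  Disaggregations sum to the totals exactly: the
#' mortality component of each year's HALY gain is split across diseases in
#' proportion to their mortality-rate reduction, the morbidity component by
#' each disease's own prevalence x disability-weight term.
#'
#' @param state model state from [build_model()].
#' @param pifs data.frame `sex, age_band, disease, pif` (rows absent = 0).
#' @param horizon_years number of annual cycles (>= 1).
#' @param discount_rate annual discount rate applied to HALYs and costs
#'   (default 0).
#' @param detail also return the per-sex life-table columns (survivors `l`,
#'   life years `L`, disability adjustment `w`, health-adjusted life years
#'   `Lw` for both arms) as the `detail` element; off by default.
#' @return object of class `slt_output`: list with `by` (per sex x disease
#'   data.frame), `by_sex`, `by_disease` and `totals`.
#' @export
run_comparison <- function(state, pifs, horizon_years = 1, discount_rate = 0,
                           detail = FALSE) {
  if (horizon_years < 1) abort_domain("horizon_years must be >= 1")
  H <- as.integer(horizon_years)
  if (nrow(pifs)) {
    require_columns(pifs, c("sex", "age_band", "disease", "pif"), "PIF table")
    bad <- setdiff(unique(pifs$disease), names(state$epi))
    if (length(bad)) {
      abort_validation(sprintf("PIFs refer to unknown disease(s): %s",
                               paste(bad, collapse = ", ")))
    }
    if (any(!pifs$sex %in% SEXES)) abort_validation("PIF table has unknown sex labels")
    if (any(pifs$pif > 1)) abort_validation("PIF values must be <= 1")
  }
  ages <- state$ages
  n <- length(ages)
  a0 <- ages[1]
  amax <- ages[n]
  rows <- list()
  details <- list()
  for (sex in state$sexes) {
    popsl <- state$pop[state$pop$sex == sex, ]
    popsl <- popsl[order(popsl$age), ]
    N <- popsl$population
    m_all <- popsl$all_cause_mortality
    w_tot <- popsl$total_yld_rate
    dis <- names(state$epi)
    dis <- dis[vapply(dis, function(d) sex %in% disease_sexes(state$defs, d), logical(1))]
    nd <- length(dis)

    # pass 1: per-disease average-prevalence trajectories for both arms
    pb_b <- pb_s <- ii_b <- ii_s <- ff <- dw_t <- cst <- basis_per_prev <-
      vector("list", nd)
    for (di in seq_along(dis)) {
      d <- dis[di]
      epi <- state$epi[[d]]
      sl <- epi[epi$sex == sex, ]
      sl <- sl[order(sl$age), ]
      i0 <- sl$incidence
      pif_age <- numeric(n)
      if (nrow(pifs)) {
        psl <- pifs[pifs$disease == d & pifs$sex == sex, ]
        for (k in seq_len(nrow(psl))) {
          band_ages <- ages_in_band(psl$age_band[k], min_age = a0, max_age = amax)
          pif_age[match(band_ages, ages)] <- psl$pif[k]
        }
      }
      i1 <- i0 * (1 - pif_age)
      s_b <- 1 - sl$prevalence; c_b <- sl$prevalence
      s_s <- s_b; c_s <- c_b
      Pb <- Ps <- Ib <- Is_ <- Fm <- Dw <- matrix(0, H, n)
      for (t in 0:(H - 1)) {
        ai <- pmin(ages + t, amax) - a0 + 1
        mu_t <- m_all[ai]
        f_t <- sl$case_fatality[ai]
        stb <- id_step_closed(s_b, c_b, i0[ai], f_t, mu_t)
        sts <- id_step_closed(s_s, c_s, i1[ai], f_t, mu_t)
        Pb[t + 1, ] <- stb$Ic / (stb$Is + stb$Ic)
        Ps[t + 1, ] <- sts$Ic / (sts$Is + sts$Ic)
        Ib[t + 1, ] <- i0[ai]
        Is_[t + 1, ] <- i1[ai]
        Fm[t + 1, ] <- f_t
        Dw[t + 1, ] <- sl$disability_weight[ai]
        tb <- stb$s1 + stb$c1; s_b <- stb$s1 / tb; c_b <- stb$c1 / tb
        ts_ <- sts$s1 + sts$c1; s_s <- sts$s1 / ts_; c_s <- sts$c1 / ts_
      }
      pb_b[[di]] <- Pb; pb_s[[di]] <- Ps; ii_b[[di]] <- Ib; ii_s[[di]] <- Is_
      ff[[di]] <- Fm; dw_t[[di]] <- Dw
      cst[[di]] <- cost_by_age(state$costs, d, sex, ages)
      basis_per_prev[[di]] <-
        state$defs$cost_basis[state$defs$name == d] == "per_prevalent_case"
    }

    # pass 2: shared life-table columns and per-disease attribution
    haly <- deaths <- cases <- cost <- setNames(numeric(nd), dis)
    l_b <- l_s <- N
    if (detail) {
      det <- list(l_bau = matrix(NA_real_, H + 1, n), l_scn = matrix(NA_real_, H + 1, n),
                  L_bau = matrix(NA_real_, H, n), L_scn = matrix(NA_real_, H, n),
                  w_bau = matrix(NA_real_, H, n), w_scn = matrix(NA_real_, H, n),
                  Lw_bau = matrix(NA_real_, H, n), Lw_scn = matrix(NA_real_, H, n))
      det$l_bau[1, ] <- l_b
      det$l_scn[1, ] <- l_s
    }
    for (t in 0:(H - 1)) {
      ai <- pmin(ages + t, amax) - a0 + 1
      dm <- matrix(0, n, max(nd, 1))
      dwc <- matrix(0, n, max(nd, 1))
      for (di in seq_along(dis)) {
        dp <- pb_b[[di]][t + 1, ] - pb_s[[di]][t + 1, ]
        dm[, di] <- ff[[di]][t + 1, ] * dp
        dwc[, di] <- dw_t[[di]][t + 1, ] * dp
      }
      m_b <- m_all[ai]
      dm_sum <- rowSums(dm)
      m_s <- pmax(m_b - dm_sum, 0)
      mort_red <- m_b - m_s
      q_b <- 1 - exp(-m_b)
      q_s <- 1 - exp(-m_s)
      l_b1 <- l_b * (1 - q_b)
      l_s1 <- l_s * (1 - q_s)
      L_b <- (l_b + l_b1) / 2
      L_s <- (l_s + l_s1) / 2
      w_b <- pmin(pmax(w_tot[ai], 0), 1)
      dwc_sum <- rowSums(dwc)
      w_s <- pmin(pmax(w_b - dwc_sum, 0), 1)
      morb_red <- w_b - w_s
      v <- (1 + discount_rate)^(-t)
      mort_share_den <- ifelse(dm_sum != 0, dm_sum, 1)
      morb_share_den <- ifelse(dwc_sum != 0, dwc_sum, 1)
      for (di in seq_along(dis)) {
        sh_m <- dm[, di] / mort_share_den      # fraction of mortality reduction
        sh_w <- dwc[, di] / morb_share_den     # fraction of morbidity reduction
        haly[di] <- haly[di] + v * sum(
          (L_s - L_b) * (1 - w_s) * sh_m + L_b * sh_w * morb_red)
        deaths[di] <- deaths[di] + sum(L_b * sh_m * mort_red)
        case_age <- L_b * (1 - pb_b[[di]][t + 1, ]) * ii_b[[di]][t + 1, ] -
          L_s * (1 - pb_s[[di]][t + 1, ]) * ii_s[[di]][t + 1, ]
        cases[di] <- cases[di] + sum(case_age)
        if (basis_per_prev[[di]]) {
          cost[di] <- cost[di] + v * sum(
            (L_b * pb_b[[di]][t + 1, ] - L_s * pb_s[[di]][t + 1, ]) * cst[[di]][ai])
        } else {
          cost[di] <- cost[di] + v * sum(case_age * cst[[di]][ai])
        }
      }
      if (detail) {
        det$l_bau[t + 2, ] <- l_b1; det$l_scn[t + 2, ] <- l_s1
        det$L_bau[t + 1, ] <- L_b; det$L_scn[t + 1, ] <- L_s
        det$w_bau[t + 1, ] <- w_b; det$w_scn[t + 1, ] <- w_s
        det$Lw_bau[t + 1, ] <- L_b * (1 - w_b); det$Lw_scn[t + 1, ] <- L_s * (1 - w_s)
      }
      l_b <- l_b1
      l_s <- l_s1
    }
    if (detail) details[[sex]] <- det
    if (nd) {
      rows[[sex]] <- data.frame(sex = sex, disease = dis,
                                halys_gained = unname(haly),
                                cost_offset = unname(cost),
                                deaths_averted = unname(deaths),
                                incident_cases_prevented = unname(cases))
    }
  }
  by <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sex = character(), disease = character(), halys_gained = numeric(),
               cost_offset = numeric(), deaths_averted = numeric(),
               incident_cases_prevented = numeric())
  rownames(by) <- NULL
  metrics <- c("halys_gained", "cost_offset", "deaths_averted",
               "incident_cases_prevented")
  agg <- function(key) {
    if (!nrow(by)) return(by)
    stats::aggregate(by[metrics], by = by[key], FUN = sum)
  }
  structure(list(
    by = by,
    by_sex = agg("sex"),
    by_disease = agg("disease"),
    totals = vapply(metrics, function(m) sum(by[[m]]), numeric(1)),
    detail = if (detail) details else NULL,
    horizon_years = H,
    discount_rate = discount_rate
  ), class = "slt_output")
}

#' @export
print.slt_output <- function(x, ...) {
  cat(sprintf("Life-table comparison (horizon %d y, discount %.1f%%)\n",
              x$horizon_years, 100 * x$discount_rate))
  cat(sprintf("  HALYs gained:             %12.1f\n", x$totals[["halys_gained"]]))
  cat(sprintf("  Healthcare cost offset:   A$%10.0f\n", x$totals[["cost_offset"]]))
  cat(sprintf("  Deaths averted:           %12.1f\n", x$totals[["deaths_averted"]]))
  cat(sprintf("  Incident cases prevented: %12.1f\n",
              x$totals[["incident_cases_prevented"]]))
  invisible(x)
}
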