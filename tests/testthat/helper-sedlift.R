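# Shared fixtures and independent oracles.  Oracles deliberately avoid the
# package's production code paths.

Z <- qnorm(0.975)

# small synthetic bundle for fast life-table tests
make_bundle <- function(seed = 1, ages = 45:75, total_population = 2e6) {
  generate_bundle(synth_config(seed = seed, ages = ages,
                               total_population = total_population))
}

# independent fine-grid Euler integrator for the illness-death system;
# rates are constant within each year, `years` one-year intervals
euler_illness_death <- function(i, f, r, mu, years, dt = 1e-4,
                                init = c(1, 0, 0, 0)) {
  i <- rep_len(i, years); f <- rep_len(f, years)
  r <- rep_len(r, years); mu <- rep_len(mu, years)
  n_sub <- round(1 / dt)
  S <- numeric(years + 1); C <- numeric(years + 1)
  Dd <- numeric(years + 1); Do <- numeric(years + 1)
  S[1] <- init[1]; C[1] <- init[2]; Dd[1] <- init[3]; Do[1] <- init[4]
  s <- init[1]; c <- init[2]; dd <- init[3]; do_ <- init[4]
  for (y in seq_len(years)) {
    iy <- i[y]; fy <- f[y]; ry <- r[y]; my <- mu[y]
    for (k in seq_len(n_sub)) {
      ds <- (-(iy + my) * s + ry * c) * dt
      dc <- (iy * s - (ry + fy + my) * c) * dt
      ddd <- fy * c * dt
      ddo <- my * (s + c) * dt
      s <- s + ds; c <- c + dc; dd <- dd + ddd; do_ <- do_ + ddo
    }
    S[y + 1] <- s; C[y + 1] <- c; Dd[y + 1] <- dd; Do[y + 1] <- do_
  }
  data.frame(age = 0:years, S = S, C = C, Dd = Dd, Do = Do, p = C / (S + C))
}

# brute-force REML: grid search of the restricted log-likelihood over tau2
reml_grid_oracle <- function(y, v, grid = seq(0, 1, by = 1e-5)) {
  ll <- vapply(grid, function(t2) {
    w <- 1 / (v + t2)
    mu <- sum(w * y) / sum(w)
    -0.5 * (sum(log(v + t2)) + log(sum(w)) + sum(w * (y - mu)^2))
  }, numeric(1))
  t2 <- grid[which.max(ll)]
  w <- 1 / (v + t2)
  list(tau2 = t2, mu = sum(w * y) / sum(w))
}

# build a study-effects data.frame from log-RRs and their SEs
studies_from_log <- function(y, se, disease = "d", contrast = "high_vs_low") {
  data.frame(study_id = seq_along(y), disease = disease, contrast = contrast,
             rr = exp(y), ci_low = exp(y - Z * se), ci_high = exp(y + Z * se))
}

# sum of a metric across the per-sex/disease breakdown
total_of <- function(out, metric) out$totals[[metric]]
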