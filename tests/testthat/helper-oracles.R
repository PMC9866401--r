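# Independent oracles used across the suite. These never call the code
# paths they check.

# Closed-form stationary points of the two models that admit them,
# obtained by solving dr/dT = 0 analytically.
topt_closed_kontodimas <- function(CTmin, CTmax) (2 * CTmax + CTmin) / 3

topt_closed_briere1 <- function(CTmin, CTmax) {
  (4 * CTmax + 3 * CTmin +
     sqrt(16 * CTmax^2 + 9 * CTmin^2 - 16 * CTmin * CTmax)) / 10
}

# Numeric-integration oracle for the probability that total development
# time exceeds the deadline, with stage rates independent truncated
# normals N(tau_j, cv*tau_j) on [0, Inf). Integrates over the egg and
# larval rates on a fine grid and uses the analytic truncated-normal CDF
# for the pupal rate: P(d > D) = E[ P(1/r3 > D - 1/r1 - 1/r2) ].
failure_prob_quadrature <- function(model, temp, deadline, n_grid = 241) {
  taus <- vapply(model$stages, tpc_rate, numeric(1), temp = temp)
  if (any(taus <= 0)) return(1)
  sds <- model$cv * taus
  if (all(sds == 0)) return(as.numeric(sum(1 / taus) > deadline))
  Z <- 1 - pnorm(0, taus, sds)
  axis <- function(j) {
    lo <- max(1e-12, taus[j] - 8 * sds[j])
    hi <- taus[j] + 8 * sds[j]
    x <- seq(lo, hi, length.out = n_grid)
    w <- dnorm(x, taus[j], sds[j])
    w <- w / sum(w)  # normalised discrete weights on the truncated support
    list(x = x, w = w)
  }
  a1 <- axis(1); a2 <- axis(2)
  t12 <- outer(1 / a1$x, 1 / a2$x, "+")
  rem <- deadline - t12
  p3_below <- function(r) (pnorm(r, taus[3], sds[3]) -
                           pnorm(0, taus[3], sds[3])) / Z[3]
  P <- matrix(1, n_grid, n_grid)
  pos <- rem > 0
  P[pos] <- p3_below(1 / rem[pos])
  as.numeric(t(a1$w) %*% P %*% a2$w)
}

# Deterministic crossing of the summed mean stage times against the
# deadline, by bisection on the total-time curve (cv = 0 limit).
deterministic_crossings <- function(model, deadline, tol = 1e-4) {
  total_time <- function(T) {
    taus <- vapply(model$stages, tpc_rate, numeric(1), temp = T)
    if (any(taus <= 0)) Inf else sum(1 / taus)
  }
  grid <- seq(0, 50, by = 0.1)
  ok <- vapply(grid, function(T) total_time(T) <= deadline, logical(1))
  if (!any(ok)) return(c(NA_real_, NA_real_))
  lo_i <- which(ok)[1]; hi_i <- max(which(ok))
  bisect <- function(bad, good) {
    while (abs(good - bad) > tol) {
      mid <- (bad + good) / 2
      if (total_time(mid) <= deadline) good <- mid else bad <- mid
    }
    good
  }
  c(bisect(grid[lo_i - 1], grid[lo_i]), bisect(grid[hi_i + 1], grid[hi_i]))
}

# Small zero-noise observation builder used by the fitting tests.
noiseless_obs <- function(params, temps, stage = "larva", study = "S1") {
  rate_observations("synthetic_sp", stage, study, temps,
                    1 / tpc_rate(params, temps))
}
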