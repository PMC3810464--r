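# Canonical parameter sets used across the suite.
# The symmetric set mu = 0.05, D = 1, r = 1/2 is the reference point for
# the single-sex reduction; mu = 0.03 (deeper in the spreading regime,
# faster fronts, smaller critical clusters) keeps PDE-heavy tests cheap.
p_sym05 <- function() model_params(0.5, 0.05, 0.05)
p_sym03 <- function() model_params(0.5, 0.03, 0.03)
ss05 <- function() single_sex_params(0.05, 1)
ss03 <- function() single_sex_params(0.03, 1)

# Random admissible two-sex parameter sets (positive equilibria exist),
# drawn with a stability margin so numerical oracles converge briskly.
rand_admissible <- function(n, seed = 1, sigma = 1) {
  set.seed(seed)
  out <- vector("list", n)
  i <- 0
  while (i < n) {
    r <- runif(1, 0.15, 0.85)
    mu_f <- runif(1, 0.005, 0.06)
    mu_m <- runif(1, 0.005, 0.06)
    A <- mu_f / r + mu_m / (1 - r)
    if (A < 0.9 * sigma / 4) {
      i <- i + 1
      out[[i]] <- model_params(r, mu_f, mu_m,
                               D_f = runif(1, 0.25, 4),
                               D_m = runif(1, 0.25, 4), sigma = sigma)
    }
  }
  out
}

# 0-D (non-spatial) oracle: long-time limit of the local dynamics from a
# given start, via an adaptive ODE solver, independent of the PDE kernel.
ode0d_final <- function(f0, m0, params, t_end = 5000) {
  rhs <- function(t, y, parms) {
    rr <- local_rates(max(y[1], 0), max(y[2], 0), params)
    list(c(rr$df_dt, rr$dm_dt))
  }
  sol <- deSolve::ode(c(f = unname(f0), m = unname(m0)), c(0, t_end), rhs,
                      NULL, rtol = 1e-10, atol = 1e-12)
  sol[nrow(sol), c("f", "m")]
}
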