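test_that("local rates have the mass-action/self-regulation structure", {
  p <- p_sym05()
  # no females: births stop, males decay exponentially
  r0 <- local_rates(0, 0.3, p)
  expect_equal(r0$df_dt, 0)
  expect_equal(r0$dm_dt, -p$mu_m * 0.3)
  # extinction is a fixed point
  expect_equal(unlist(local_rates(0, 0, p)), c(df_dt = 0, dm_dt = 0))
  # negative densities rejected
  expect_error(local_rates(-0.1, 0.2, p), "non-negative")
  # vectorized evaluation matches scalar
  f <- c(0.1, 0.2); m <- c(0.3, 0.1)
  rv <- local_rates(f, m, p)
  expect_equal(rv$df_dt[2], local_rates(0.2, 0.1, p)$df_dt)
})

test_that("closed-form equilibria zero the rates and are classified correctly", {
  for (params in rand_admissible(40, seed = 11)) {
    eq <- equilibria(params)
    expect_true(eq$exists)
    for (pt in list(eq$allee, eq$persistence)) {
      rr <- local_rates(pt["f"], pt["m"], params)
      expect_lt(abs(rr$df_dt), 1e-10)
      expect_lt(abs(rr$dm_dt), 1e-10)
    }
    # ordering of totals inside the occupancy simplex
    expect_gt(eq$allee_total, 0)
    expect_lt(eq$allee_total, eq$persistence_total)
    expect_lt(eq$persistence_total, 1)
    # vacant-fraction roots solve s(1-s) = A/sigma
    A <- params$mu_f / params$r + params$mu_m / (1 - params$r)
    for (s in eq$s_values)
      expect_equal(s * (1 - s), A / params$sigma, tolerance = 1e-12)
    # Jacobian classification: persistence attracting, Allee a saddle
    expect_true(all(Re(eq$eigenvalues$persistence) < 0))
    expect_true(any(Re(eq$eigenvalues$allee) > 0))
    expect_true(all(Re(eq$eigenvalues$extinction) < 0))
  }
})

test_that("stability condition matches equilibrium existence everywhere", {
  set.seed(21)
  n_checked <- 0
  for (i in 1:1000) {
    params <- model_params(runif(1, 0.02, 0.98), runif(1, 1e-3, 0.2),
                           runif(1, 1e-3, 0.2))
    expect_identical(stability_condition_two_sex(params),
                     equilibria(params)$exists)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 1000)
  # arithmetic anchor cases: A = 0.2 < 1/4; boundary equality is not stable
  expect_true(stability_condition_two_sex(model_params(0.5, 0.05, 0.05)))
  expect_false(stability_condition_two_sex(model_params(0.5, 0.0625, 0.0625)))
  expect_false(stability_condition_two_sex(model_params(1e-6, 0.05, 0.05)))
  # single-sex form agrees with the symmetric restriction
  for (mu in c(0.01, 0.05, 0.0625, 0.1)) {
    expect_identical(stability_condition_single_sex(single_sex_params(mu)),
                     stability_condition_two_sex(model_params(0.5, mu, mu)))
  }
  expect_true(stability_condition_single_sex(single_sex_params(0.05)))
  expect_false(stability_condition_single_sex(single_sex_params(1 / 16)))
  expect_false(stability_condition_single_sex(single_sex_params(0.1)))
})

test_that("single-sex rate is the exact symmetric reduction", {
  p2 <- p_sym05()
  p1 <- as_single_sex(p2)
  set.seed(3)
  u <- runif(100, 0, 0.5)
  rr <- local_rates(u, u, p2)
  g <- single_sex_rate(u, p1)
  expect_equal(rr$df_dt, g, tolerance = 1e-14)
  expect_equal(rr$dm_dt, g, tolerance = 1e-14)
  # sign pattern of the cubic in the bistable regime
  roots <- single_sex_roots(p1)
  u_in <- seq(roots$u_minus * 0.05, roots$u_minus * 0.95, length.out = 25)
  u_mid <- seq(roots$u_minus * 1.05, roots$u_plus * 0.95, length.out = 25)
  expect_true(all(single_sex_rate(u_in, p1) < 0))
  expect_true(all(single_sex_rate(u_mid, p1) > 0))
})

test_that("symmetric two-sex equilibria match the single-sex closed form", {
  for (mu in c(0.01, 0.03, 0.05, 0.06)) {
    eq <- equilibria(model_params(0.5, mu, mu))
    roots <- single_sex_roots(single_sex_params(mu))
    expect_equal(unname(eq$persistence["f"]), roots$u_plus, tolerance = 1e-12)
    expect_equal(unname(eq$persistence["m"]), roots$u_plus, tolerance = 1e-12)
    expect_equal(unname(eq$allee["f"]), roots$u_minus, tolerance = 1e-12)
    expect_equal(eq$persistence_total, 2 * roots$u_plus, tolerance = 1e-12)
  }
  # mu -> 0: carrying density approaches 1/2 per sex
  eq0 <- equilibria(model_params(0.5, 1e-9, 1e-9))
  expect_equal(unname(eq0$persistence["f"]), 0.5, tolerance = 1e-6)
})

test_that("optimal sex ratio maximizes equilibrium density", {
  expect_equal(optimal_sex_ratio(0.05, 0.05), 0.5)
  expect_equal(optimal_sex_ratio(0.04, 0.01), 2 / 3, tolerance = 1e-12)

  grid_argmax <- function(mu_f, mu_m, step = 1e-4) {
    rr <- seq(step, 1 - step, by = step)
    tot <- vapply(rr, function(r) {
      pp <- model_params(r, mu_f, mu_m)
      eq <- equilibria(pp)
      if (eq$exists) eq$persistence_total else -Inf
    }, numeric(1))
    rr[which.max(tot)]
  }
  set.seed(7)
  for (i in 1:6) {
    mu_f <- runif(1, 0.005, 0.05); mu_m <- runif(1, 0.005, 0.05)
    expect_equal(optimal_sex_ratio(mu_f, mu_m), grid_argmax(mu_f, mu_m),
                 tolerance = 1e-3)
  }
  # r* lies strictly inside the admissible band
  for (i in 1:50) {
    mu_f <- runif(1, 0.002, 0.04); mu_m <- runif(1, 0.002, 0.04)
    band <- admissible_r_range(mu_f, mu_m)
    rs <- optimal_sex_ratio(mu_f, mu_m)
    expect_gt(rs, band[1]); expect_lt(rs, band[2])
  }
})

test_that("equilibrium density is unimodal in r with the peak at r*", {
  mu_f <- 0.04; mu_m <- 0.01
  band <- admissible_r_range(mu_f, mu_m)
  rr <- seq(band[1] + 1e-3, band[2] - 1e-3, by = 1e-3)
  tot <- vapply(rr, function(r)
    equilibria(model_params(r, mu_f, mu_m))$persistence_total, numeric(1))
  peak <- which.max(tot)
  expect_equal(rr[peak], optimal_sex_ratio(mu_f, mu_m), tolerance = 2e-3)
  expect_true(all(diff(tot[1:peak]) > 0))
  expect_true(all(diff(tot[peak:length(tot)]) < 0))
})
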