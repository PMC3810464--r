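test_that("homogeneous fixed points are invariant under one Euler step", {
  p <- p_sym05()
  eq <- equilibria(p)
  grid <- grid_1d(30, 61)
  st <- state_field(rep(eq$persistence["f"], 61), rep(eq$persistence["m"], 61))
  st1 <- step(st, p, grid)
  expect_lt(max(abs(st1$f - st$f)), 1e-12)
  expect_lt(max(abs(st1$m - st$m)), 1e-12)
  z <- step(state_field(rep(0, 61), rep(0, 61)), p, grid)
  expect_identical(max(z$f, z$m), 0)
})

test_that("the equation symmetry f = m is preserved exactly by the scheme", {
  p <- p_sym05()
  grid <- grid_1d(30, 61)
  u0 <- 0.4 * exp(-(grid$x - 15)^2 / 4)
  st <- step(state_field(u0, u0), p, grid, n_steps = 500)
  expect_identical(max(abs(st$f - st$m)), 0)
})

test_that("homogeneous initial states follow the 0-D dynamics oracle", {
  p <- p_sym05()
  eq <- equilibria(p)
  grid <- grid_1d(30, 61)
  cfg <- integration_config(max_time = 5e4)
  # below the Allee point: extinction (oracle agrees)
  lo <- 0.9 * eq$allee
  res <- integrate_to_equilibrium(state_field(rep(lo["f"], 61), rep(lo["m"], 61)),
                                  p, grid, cfg)
  expect_identical(res$outcome$label, "EXTINCTION")
  expect_lt(sum(ode0d_final(lo["f"], lo["m"], p)), 1e-6)
  # at 90% of the persistence point: restoration
  hi <- 0.9 * eq$persistence
  res <- integrate_to_equilibrium(state_field(rep(hi["f"], 61), rep(hi["m"], 61)),
                                  p, grid, cfg)
  expect_identical(res$outcome$label, "PERSISTENCE")
  expect_equal(sum(ode0d_final(hi["f"], hi["m"], p)), eq$persistence_total,
               tolerance = 1e-6)
})

test_that("single-sex runs reproduce the scalar fixed points and basins", {
  p1 <- ss05()
  roots <- single_sex_roots(p1)
  grid <- grid_1d(30, 61)
  res <- run_single_sex(rep(roots$u_plus, 61), p1, grid)
  expect_identical(res$outcome$label, "PERSISTENCE")
  expect_lt(max(abs(res$u - roots$u_plus)), 1e-8)
  res <- run_single_sex(rep(roots$u_minus * 0.99, 61), p1, grid)
  expect_identical(res$outcome$label, "EXTINCTION")
})

test_that("rectangular two-sex clusters far above critical restore", {
  p <- p_sym03()
  eq <- equilibria(p)
  grid <- grid_1d(90, 361)
  st <- rectangular_ic(grid, eq$persistence["f"], eq$persistence["m"], 15, 15)
  res <- integrate_to_equilibrium(st, p, grid)
  expect_identical(res$outcome$label, "PERSISTENCE")
  # cross-check at doubled resolution
  grid2 <- grid_1d(90, 721)
  st2 <- rectangular_ic(grid2, eq$persistence["f"], eq$persistence["m"], 15, 15)
  res2 <- integrate_to_equilibrium(st2, p, grid2)
  expect_identical(res2$outcome$label, "PERSISTENCE")
})

test_that("symmetric two-sex and single-sex trajectories agree to the bit", {
  p1 <- ss05()
  p2 <- as_two_sex(p1)
  grid <- grid_1d(60, 161)
  u0 <- 0.35 * (abs(grid$x - 30) < 8)
  cfg <- integration_config(record_every = 25, max_time = 250)
  a <- integrate_to_equilibrium(state_field(u0, u0), p2, grid, cfg,
                                early_exit = FALSE)
  b <- run_single_sex(u0, p1, grid, cfg, early_exit = FALSE)
  expect_identical(dim(a$snapshots$f), dim(b$snapshots$u))
  expect_lt(max(abs(a$snapshots$f - b$snapshots$u)), 1e-10)
  expect_lt(max(abs(a$snapshots$m - b$snapshots$u)), 1e-10)
})

test_that("the scalar comparison principle holds at recorded times", {
  p1 <- ss03()
  grid <- grid_1d(60, 121)
  cfg <- integration_config(record_every = 20, max_time = 200)
  base <- 0.4 * exp(-(grid$x - 30)^2 / 20)
  lo <- run_single_sex(base * 0.8, p1, grid, cfg, early_exit = FALSE)
  hi <- run_single_sex(base, p1, grid, cfg, early_exit = FALSE)
  expect_true(all(hi$snapshots$u - lo$snapshots$u >= -1e-14))
})

test_that("mirror symmetry and non-negativity are preserved", {
  p <- p_sym03()
  grid <- grid_1d(40, 81)
  f0 <- 0.3 * (abs(grid$x - 20) < 5)
  m0 <- 0.45 * (abs(grid$x - 20) < 3.2)
  st <- step(state_field(f0, m0), p, grid, n_steps = 2000)
  expect_lt(max(abs(st$f - rev(st$f))), 1e-10)
  expect_lt(max(abs(st$m - rev(st$m))), 1e-10)
  expect_true(all(st$f >= 0) && all(st$m >= 0))
})

test_that("divergent integrations abort with a diagnostic", {
  p <- model_params(0.5, 0.05, 0.05, D_f = 1, D_m = 1)
  grid <- grid_1d(30, 61)
  cfg <- integration_config(dt = 10)  # grossly violates the stability bound
  st <- rectangular_ic(grid, 0.3, 0.3, 10, 10)
  expect_error(integrate_to_equilibrium(st, p, grid, cfg), "diverged")
})
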