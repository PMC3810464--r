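test_that("the growth potential is the antiderivative of the growth law", {
  p <- ss05()
  expect_identical(allee_potential(0, p), 0)
  # critical points of G sit at the local equilibria
  roots <- single_sex_roots(p)
  h <- 1e-6
  for (u in c(roots$u_minus, roots$u_plus)) {
    dG <- (allee_potential(u + h, p) - allee_potential(u - h, p)) / (2 * h)
    expect_lt(abs(dG), 1e-10 + 1e-5 * h)
  }
  # quadrature oracle at 100 points
  for (u in seq(0.01, 1, length.out = 100)) {
    q <- stats::integrate(function(v) single_sex_rate(v, p), 0, u,
                          rel.tol = 1e-12)$value
    expect_equal(allee_potential(u, p), q, tolerance = 1e-10)
  }
})

test_that("the first integral is conserved along stationary orbits", {
  p <- ss05()
  sep <- separatrix_constants(p)
  # fixed points carry E = G(u*)
  expect_equal(first_integral(sep$u_minus, 0, p), sep$E_center)
  expect_equal(first_integral(sep$u_plus, 0, p), sep$E_persistence)
  # numerically integrated periodic orbit: E constant to 1e-8 relative
  E0 <- 0.5 * sep$E_center
  u_turn <- stats::uniroot(function(u) allee_potential(u, p) - E0,
                           c(1e-12, sep$u_minus))$root
  rhs <- function(x, y, parms)
    list(c(y[2], -single_sex_rate(max(y[1], 0), p) / p$D))
  sol <- deSolve::ode(c(u = u_turn, w = 0), seq(0, 120, by = 0.1), rhs, NULL,
                      rtol = 1e-12, atol = 1e-14)
  Es <- first_integral(sol[, "u"], sol[, "w"], p)
  expect_lt(stats::sd(Es) / abs(mean(Es)), 1e-8)
})

test_that("separatrix constants and fixed-point types match the phase plane", {
  p <- ss05()
  sep <- separatrix_constants(p)
  expect_identical(sep$E_extinction, 0)
  # the center sits at the potential minimum, below both saddle values
  expect_lt(sep$E_center, min(sep$E_extinction, sep$E_persistence))
  expect_identical(unname(sep$classification),
                   c("saddle", "center", "saddle"))
  # classification agrees with the eigenvalues +/- sqrt(-g'(u*)/D)
  gp <- function(u) p$sigma * u - 3 * p$sigma * u^2 - p$mu
  expect_lt(gp(0), 0)            # real pair: saddle
  expect_lt(gp(sep$u_plus), 0)   # saddle
  expect_gt(gp(sep$u_minus), 0)  # imaginary pair: center
  expect_error(separatrix_constants(single_sex_params(0.08)), "bistable")
})

test_that("orbit periods interpolate between the harmonic limit and divergence", {
  p <- ss05()
  sep <- separatrix_constants(p)
  gp_center <- p$sigma * sep$u_minus - 3 * p$sigma * sep$u_minus^2 - p$mu
  harmonic <- 2 * pi * sqrt(p$D / gp_center)
  # vanishing amplitude: period -> 2 pi sqrt(D / g'(u_-)), not zero
  expect_equal(orbit_period(sep$E_center + 1e-8 * abs(sep$E_center), p),
               harmonic, tolerance = 1e-4)
  # approach to the separatrix: unbounded growth
  expect_gt(orbit_period(-abs(sep$E_center) * 1e-140, p),
            10 * orbit_period(-abs(sep$E_center) * 0.5, p))
  # finite and positive across a log-spaced scan of the band
  periods <- vapply(10^seq(-1, -9, by = -1), function(x)
    orbit_period(-abs(sep$E_center) * x, p), numeric(1))
  expect_true(all(is.finite(periods) & periods > 0))
  expect_true(all(diff(periods) > 0))
  expect_error(orbit_period(1e-3, p), "outside the periodic band")
})

test_that("the aperiodic profile solves the stationary equation", {
  p <- ss05()
  prof <- aperiodic_profile(p, threshold = 1e-3, dx = 0.01)
  roots <- single_sex_roots(p)
  expect_gt(prof$u_max, roots$u_minus)
  expect_lt(prof$u_max, roots$u_plus)
  expect_equal(allee_potential(prof$u_max, p), 0, tolerance = 1e-13)
  # mirror symmetry about the peak
  expect_identical(prof$u, rev(prof$u))
  # interior residual of D u'' + g(u), 4th-order stencil
  g_scale <- max(abs(single_sex_rate(prof$u, p)))
  expect_lt(stationary_residual(prof, order = 4), 1e-6 * g_scale)
})

test_that("profile width and cost obey the diffusion rescaling symmetry", {
  # x -> 2x maps D to 4D: width and area double exactly in the continuum
  pr1 <- aperiodic_profile(single_sex_params(0.05, D = 1),
                           threshold = 1e-4, dx = 0.02)
  pr4 <- aperiodic_profile(single_sex_params(0.05, D = 4),
                           threshold = 1e-4, dx = 0.04)
  expect_equal(max(pr4$x) / max(pr1$x), 2, tolerance = 1e-3)
  expect_equal(pr4$cost / pr1$cost, 2, tolerance = 1e-3)
})

test_that("profile cost decreases with the truncation threshold and converges", {
  p <- ss05()
  costs <- vapply(c(3e-2, 1e-2, 3e-3, 1e-3, 3e-4),
                  function(th) aperiodic_profile(p, th, dx = 0.05)$cost,
                  numeric(1))
  expect_true(all(diff(costs) > 0))        # lower threshold, larger cost
  expect_lt(costs[5] - costs[4], costs[2] - costs[1])  # converging tail
  prof <- aperiodic_profile(p, 1e-3, dx = 0.05)
  expect_gt(prof$cost_with_tail, prof$cost)
  expect_lt(prof$cost_with_tail - prof$cost, 0.05 * prof$cost)
})

test_that("the homoclinic construction requires the spreading regime", {
  # bistable but beyond the Maxwell point (1/18 < mu < 1/16): fronts recede
  expect_error(aperiodic_profile(single_sex_params(0.058)), "non-spreading")
  expect_error(aperiodic_profile(single_sex_params(0.08)), "bistable")
})

test_that("scaled nucleus tips into restoration or extinction", {
  p1 <- ss03()
  p2 <- as_two_sex(p1)
  prof <- aperiodic_profile(p1, threshold = 1e-3, dx = 0.25)
  grid <- grid_1d(3 * max(prof$x) * 2, round(6 * max(prof$x) / 0.25) + 1)
  up <- profile_on_grid(prof, grid, scale = 1.05)
  dn <- profile_on_grid(prof, grid, scale = 0.95)
  expect_identical(
    integrate_to_equilibrium(state_field(up, up), p2, grid)$outcome$label,
    "PERSISTENCE")
  expect_identical(
    integrate_to_equilibrium(state_field(dn, dn), p2, grid)$outcome$label,
    "EXTINCTION")
})
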