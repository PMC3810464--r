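# a small feasible reference setup shared by the annealing tests
anneal_setup <- function(dx = 0.35) {
  p <- p_sym03()
  cl <- critical_length(p, dx = dx)
  st <- rectangular_ic(cl$grid, cl$n_f, cl$n_m, cl$bracket[2], cl$bracket[2])
  list(p = p, grid = cl$grid, cl = cl,
       init = shape_state(st$f, st$m, cl$grid$dx))
}

test_that("shape states track support and cost consistently", {
  f <- c(0, 0, 0.2, 0.3, 0, 0); m <- c(0, 0.1, 0.2, 0, 0, 0)
  s <- shape_state(f, m, dx = 0.5)
  expect_identical(s$support, c(2L, 4L))
  expect_equal(s$cost, (sum(f) + sum(m)) * 0.5, tolerance = 1e-12)
  expect_error(shape_state(-f, m, 0.5), "non-negative")
})

test_that("proposals perturb, grow and shrink as configured", {
  set.seed(99)
  f <- c(rep(0, 10), rep(0.3, 20), rep(0, 10))
  s <- shape_state(f, f, dx = 0.5)
  # zero amplitude: the proposal operator is the identity
  expect_identical(propose_shape(s, 0), s)
  sex_width <- function(v) if (any(v > 0)) diff(range(which(v > 0))) else -1L
  grew <- shrank <- FALSE
  for (i in 1:1000) {
    pr <- propose_shape(s, 0.05)
    # cost change equals dx times the total density change
    expect_lt(abs((pr$cost - s$cost) -
                    (sum(pr$f - s$f) + sum(pr$m - s$m)) * s$dx), 1e-12)
    expect_true(all(pr$f + pr$m <= 1 + 1e-12))
    w0 <- sex_width(s$f); w1 <- sex_width(pr$f)
    w0m <- sex_width(s$m); w1m <- sex_width(pr$m)
    if (w1 > w0 || w1m > w0m) grew <- TRUE
    if (w1 < w0 || w1m < w0m) shrank <- TRUE
  }
  expect_true(grew)
  expect_true(shrank)
})

test_that("feasibility is decided by the PDE restoration outcome", {
  su <- anneal_setup()
  expect_true(feasible(su$init, su$p, su$grid))
  zero <- shape_state(numeric(su$grid$n_points), numeric(su$grid$n_points),
                      su$grid$dx)
  expect_false(feasible(zero, su$p, su$grid))
  # the nucleus scaled up by 5% restores
  prof <- aperiodic_profile(as_single_sex(su$p), threshold = 1e-3,
                            dx = su$grid$dx)
  grid2 <- grid_1d(4 * max(prof$x), round(4 * max(prof$x) / 0.35) + 1)
  u <- profile_on_grid(prof, grid2, scale = 1.05)
  expect_true(feasible(shape_state(u, u, grid2$dx), su$p, grid2))
})

test_that("annealing is reproducible and only improves the best cost", {
  su <- anneal_setup()
  cfg <- anneal_config(max_stages = 3, moves_per_stage = 40, seed = 5,
                       T0 = 0.01)
  r1 <- anneal(su$p, su$grid, cfg, su$init)
  r2 <- anneal(su$p, su$grid, cfg, su$init)
  expect_identical(r1$trace, r2$trace)
  expect_lte(r1$cost, su$init$cost)
  expect_true(all(diff(r1$trace$best_cost) <= 1e-12))
  expect_true(feasible(r1$state, su$p, su$grid))
  # infeasible starting point is refused
  tiny <- shape_state(c(0.2, rep(0, su$grid$n_points - 1)),
                      c(0.2, rep(0, su$grid$n_points - 1)), su$grid$dx)
  expect_error(anneal(su$p, su$grid, cfg, tiny), "not feasible")
})

test_that("converged shapes show the expected phenomenology", {
  su <- anneal_setup()
  eq <- equilibria(su$p)
  w0 <- diff(su$init$support)
  for (seed in 1:3) {
    cfg <- anneal_config(max_stages = 5, moves_per_stage = 60, seed = seed,
                         T0 = 0.01)
    res <- anneal(su$p, su$grid, cfg, su$init)
    st <- res$state
    # the substantive support (cells above one move amplitude) does not
    # grow relative to the initial rectangle; freshly seeded edge cells of
    # near-zero density are transient roughness, not spread
    amp0 <- res$diagnostics$amplitude
    solid <- which(st$f + st$m > amp0)
    expect_lte(diff(range(solid)), w0 + 2)
    # per-sex peaks stay between the Allee and persistence densities
    # (up to one move amplitude of roughening)
    amp <- res$diagnostics$amplitude
    expect_lte(max(st$f), eq$persistence["f"] + amp + 1e-9)
    expect_gte(max(st$f), eq$allee["f"])
    expect_lte(max(st$m), eq$persistence["m"] + amp + 1e-9)
    expect_gte(max(st$m), eq$allee["m"])
    # unimodal after light smoothing: the half-maximum region is one
    # contiguous arch, not split clusters
    total <- st$f + st$m
    sm <- stats::filter(total, rep(1 / 5, 5), sides = 2)
    sm[is.na(sm)] <- 0
    idx <- which(sm > max(sm) / 2)
    expect_identical(idx, seq(min(idx), max(idx)))
  }
})
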