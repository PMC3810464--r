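#' Critical male cluster length at a fixed female cluster length
#'
#' Binary search on the male cluster length `L_m`, holding the female
#' cluster length `L_f` fixed (both clusters centered). The building block
#' of the sex-specific release optimization.
#'
#' @inheritParams critical_length
#' @param L_f Fixed female cluster length (> 0).
#' @param L_max Upper bound for the male-length search.
#' @param hint Optional guess of the critical male length (e.g. the result
#'   at a neighboring `L_f`); a small bracket around it is tried before
#'   falling back to doubling, which makes the descent in
#'   [optimize_unequal()] cheap.
#' @param grid Optional [grid_1d()] to reuse across calls; defaults to a
#'   habitat sized from `L_f` and the search bound.
#' @return A `critical_result` for `L_m`. Signals a divergence error when
#'   no male length up to `L_max` rescues the population at this `L_f`.
#' @export
critical_male_length <- function(params, n_f = NULL, n_m = NULL, L_f,
                                 resolution = NULL, dx = 0.25,
                                 L_max = NULL, habitat_factor = 6,
                                 cfg = integration_config(),
                                 hint = NULL, grid = NULL) {
  stopifnot(inherits(params, "model_params"), L_f > 0)
  eq <- equilibria(params)
  if (!eq$exists)
    divergent_error("no positive equilibria: restoration impossible")
  if (is.null(n_f)) n_f <- unname(eq$persistence["f"])
  if (is.null(n_m)) n_m <- unname(eq$persistence["m"])
  if (is.null(resolution)) resolution <- dx
  maxD <- max(params$D_f, params$D_m, 1e-12)
  if (is.null(L_max)) L_max <- 50 * sqrt(maxD / min(params$mu_f, params$mu_m))
  k_max <- as.integer(ceiling(L_max / dx))
  evals <- 0L
  classify_on <- function(k, grid) {
    st <- rectangular_ic(grid, n_f, n_m, L_f, k * dx)
    evals <<- evals + 1L
    res <- integrate_to_equilibrium(st, params, grid, cfg)
    res$outcome$label == "PERSISTENCE"
  }
  k_lo <- 0L; k_hi <- NA
  if (!is.null(hint) && hint > 0) {
    k_h <- max(1L, as.integer(round(hint / dx)))
    if (is.null(grid))
      grid <- make_search_grid(habitat_factor * max(L_f, (k_h + 4) * dx), dx)
    if (classify_on(k_h, grid)) {
      k_hi <- k_h
      if (k_h > 1L && classify_on(k_h - 1L, grid)) k_hi <- k_h - 1L
      else k_lo <- k_h - 1L
    } else {
      k_lo <- k_h
      if (classify_on(k_h + 1L, grid)) k_hi <- k_h + 1L
    }
  }
  if (is.na(k_hi)) {
    k <- max(k_lo + 1L, 4L,
             as.integer(ceiling(sqrt(maxD / max(params$mu_f, params$mu_m)) / dx)))
    repeat {
      if (is.null(grid) || habitat_factor * max(L_f, k * dx) > grid$length + 1e-9)
        grid <- make_search_grid(habitat_factor * max(L_f, k * dx), dx)
      if (classify_on(k, grid)) break
      k_lo <- k
      k <- 2L * k
      if (k > k_max)
        divergent_error("no male cluster length rescues the population at this L_f")
    }
    k_hi <- k
  }
  min_gap <- max(1L, as.integer(round(resolution / dx)))
  b <- bisect_cells(function(kk) classify_on(kk, grid), k_lo, k_hi, min_gap)
  new_critical_result((b$k_lo + b$k_hi) / 2 * dx,
                      c(b$k_lo, b$k_hi) * dx, evals, "male length",
                      list(n_f = n_f, n_m = n_m, L_f = L_f, grid = grid,
                           dx = dx, k_crit = b$k_hi))
}

#' Minimize rectangular cost over sex-specific cluster lengths
#'
#' Minimizes `C(L_f) = n_f * L_f + n_m * L_m_crit(L_f)` where
#' `L_m_crit(L_f)` is the critical male length from
#' [critical_male_length()]. Starting from the equal-cluster critical
#' length, the female length moves in unit steps of one grid spacing,
#' following the direction of decreasing cost; the walk continues through
#' flat stretches (discretization plateaus) and stops once the cost has
#' increased on `patience` consecutive steps, returning the best visited
#' point. Relies on the convexity of the cost in the cluster lengths; a
#' rise-then-fall pattern in the trace beyond `nonconvex_tol` is flagged.
#'
#' @inheritParams critical_length
#' @param patience Consecutive cost increases tolerated before stopping
#'   (default 3).
#' @param max_steps Cap on descent steps per direction (default 60).
#' @param nonconvex_tol Cost tolerance for the convexity flag; `NULL`
#'   defaults to 1.5 lattice cost quanta (`max(n_f, n_m) * dx`), the
#'   noise floor of one-cell threshold quantization.
#' @return An object of class `unequal_optimum`: list with `L_f_opt`,
#'   `L_m_opt`, `cost`, `cost_equal` (equal-cluster reference),
#'   `ratio = cost / cost_equal`, `trace` (data.frame of visited
#'   `(L_f, L_m, cost)`), `nonconvex` flag and the densities used.
#' @export
optimize_unequal <- function(params, n_f = NULL, n_m = NULL,
                             resolution = NULL, dx = 0.25,
                             habitat_factor = 6,
                             cfg = integration_config(),
                             patience = 3, max_steps = 60,
                             nonconvex_tol = NULL) {
  stopifnot(inherits(params, "model_params"))
  eq <- equilibria(params)
  if (!eq$exists)
    divergent_error("no positive equilibria: restoration impossible")
  if (is.null(n_f)) n_f <- unname(eq$persistence["f"])
  if (is.null(n_m)) n_m <- unname(eq$persistence["m"])
  if (is.null(resolution)) resolution <- dx

  eq_res <- critical_length(params, n_f = n_f, n_m = n_m,
                            resolution = resolution, dx = dx,
                            habitat_factor = habitat_factor, cfg = cfg)

  # All descent evaluations share one habitat grid; the equal-cluster
  # reference is re-anchored on that same grid (threshold classifications
  # at one-cell resolution are only comparable within a single grid).
  grid <- make_search_grid(habitat_factor * max(1.5 * eq_res$bracket[2], 2), dx)
  eq_classify <- function(k) {
    st <- rectangular_ic(grid, n_f, n_m, k * dx, k * dx)
    res <- integrate_to_equilibrium(st, params, grid, cfg)
    res$outcome$label == "PERSISTENCE"
  }
  k_eq <- as.integer(round(eq_res$bracket[2] / dx))
  while (!eq_classify(k_eq)) k_eq <- k_eq + 1L
  while (k_eq > 1L && eq_classify(k_eq - 1L)) k_eq <- k_eq - 1L
  L_eq <- k_eq * dx   # smallest lattice length that persists on this grid
  cost_equal <- cost_rectangular(n_f, n_m, L_eq)
  L_m_prev <- L_eq
  if (is.null(nonconvex_tol)) nonconvex_tol <- 1.5 * max(n_f, n_m) * dx
  eval_cost <- function(L_f) {
    L_cap <- min(2.5 * (cost_equal - n_f * L_f) / n_m, grid$length / 3)
    if (L_cap <= dx) divergent_error("male-length cost budget exhausted")
    cm <- critical_male_length(params, n_f = n_f, n_m = n_m, L_f = L_f,
                               resolution = resolution, dx = dx,
                               habitat_factor = habitat_factor, cfg = cfg,
                               hint = L_m_prev, L_max = L_cap, grid = grid)
    L_m <- cm$bracket[2]
    L_m_prev <<- L_m
    list(L_m = L_m, cost = cost_rectangular(n_f, n_m, L_f, L_m))
  }

  trace <- data.frame(L_f = numeric(0), L_m = numeric(0), cost = numeric(0))
  seen <- function(L_f, res) {
    trace <<- rbind(trace, data.frame(L_f = L_f, L_m = res$L_m,
                                      cost = res$cost))
  }
  start <- eval_cost(L_eq); seen(L_eq, start)

  # probe both neighbors to pick the descent direction
  up <- eval_cost(L_eq + dx); seen(L_eq + dx, up)
  dn_Lf <- max(L_eq - dx, dx)
  dn <- tryCatch(eval_cost(dn_Lf), reintro_divergent = function(e) NULL)
  if (!is.null(dn)) seen(dn_Lf, dn)
  dir <- if (!is.null(dn) && dn$cost < up$cost) -1 else 1

  best <- trace[which.min(trace$cost), ]
  L_f <- if (dir > 0) L_eq + dx else dn_Lf
  cur <- if (dir > 0) up else dn
  rises <- if (cur$cost > start$cost + 1e-12) 1L else 0L
  steps <- 0L
  while (rises < patience && steps < max_steps) {
    L_next <- L_f + dir * dx
    if (L_next < dx / 2) break
    nxt <- tryCatch(eval_cost(L_next), reintro_divergent = function(e) NULL)
    if (is.null(nxt)) break
    seen(L_next, nxt)
    if (nxt$cost > cur$cost + 1e-12)
      rises <- rises + 1L
    else
      rises <- 0L
    cur <- nxt; L_f <- L_next; steps <- steps + 1L
  }
  best <- trace[which.min(trace$cost), ]
  # convexity flag: a strict rise followed by a strict fall in the ordered walk
  ordered <- trace[order(trace$L_f), ]
  d <- diff(ordered$cost)
  tolc <- nonconvex_tol
  rise <- d > tolc
  fall_later <- if (length(d) > 1)
    c(rev(cummax(rev(as.integer(d < -tolc))))[-1] > 0, FALSE)
  else FALSE
  nonconvex <- any(rise & fall_later)

  structure(list(L_f_opt = best$L_f, L_m_opt = best$L_m, cost = best$cost,
                 cost_equal = cost_equal, ratio = best$cost / cost_equal,
                 trace = trace, nonconvex = nonconvex,
                 n_f = n_f, n_m = n_m, L_equal = L_eq),
            class = "unequal_optimum")
}

#' @export
print.unequal_optimum <- function(x, ...) {
  cat("Sex-specific rectangular release optimum\n")
  cat(sprintf("  L_f = %.6g, L_m = %.6g, cost = %.6g\n",
              x$L_f_opt, x$L_m_opt, x$cost))
  cat(sprintf("  equal-cluster cost = %.6g, ratio = %.4f\n",
              x$cost_equal, x$ratio))
  if (x$nonconvex) cat("  WARNING: non-convex cost trace detected\n")
  invisible(x)
}
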