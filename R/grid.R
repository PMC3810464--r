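#' Uniform 1-D habitat grid
#'
#' @param length Habitat extent (length units).
#' @param n_points Number of grid nodes (>= 16).
#' @param boundary Boundary condition: `"no-flux"` (zero-gradient ghost,
#'   default — the habitat is assumed large enough that boundaries are
#'   inert) or `"absorbing"` (zero ghost).
#' @return An object of class `grid_1d` with fields `length`, `n_points`,
#'   `dx = length / (n_points - 1)`, `x` (node coordinates in `[0, length]`)
#'   and `boundary`.
#' @export
grid_1d <- function(length, n_points, boundary = c("no-flux", "absorbing")) {
  boundary <- match.arg(boundary)
  stopifnot(length > 0, n_points >= 16)
  n_points <- as.integer(n_points)
  dx <- length / (n_points - 1)
  structure(list(length = length, n_points = n_points, dx = dx,
                 x = seq(0, length, length.out = n_points),
                 boundary = boundary),
            class = "grid_1d")
}

#' @export
print.grid_1d <- function(x, ...) {
  cat(sprintf("1-D grid: [0, %.6g], %d nodes, dx = %.6g, %s boundaries\n",
              x$length, x$n_points, x$dx, x$boundary))
  invisible(x)
}

#' Integration settings for the explicit-Euler scheme
#'
#' @param dt Time step. `NULL` (default) selects
#'   `min(0.2 * dx^2 / (2 * max(D)), 0.1 / (sigma + max(mu)))` at run time:
#'   an explicit-Euler diffusion stability bound with a safety factor plus a
#'   cap against reaction stiffness.
#' @param tol_converge Equilibrium is declared when the maximum absolute
#'   time-derivative over the grid falls below this (per unit time).
#' @param max_time Cap on integrated model time.
#' @param record_every Snapshot cadence in model time units; 0 = no
#'   snapshots.
#' @return An object of class `integration_config`.
#' @export
integration_config <- function(dt = NULL, tol_converge = 1e-8,
                               max_time = 2e4, record_every = 0) {
  stopifnot(is.null(dt) || dt > 0, tol_converge > 0, max_time > 0,
            record_every >= 0)
  structure(list(dt = dt, tol_converge = tol_converge, max_time = max_time,
                 record_every = record_every),
            class = "integration_config")
}

resolve_dt <- function(cfg, params, grid, safety = 0.2) {
  if (!is.null(cfg$dt)) return(cfg$dt)
  if (inherits(params, "single_sex_params")) {
    maxD <- params$D
    react <- params$sigma + params$mu
  } else {
    maxD <- max(params$D_f, params$D_m)
    react <- params$sigma + max(params$mu_f, params$mu_m)
  }
  dt_react <- 0.1 / react
  if (maxD <= 0) return(dt_react)
  min(safety * grid$dx^2 / (2 * maxD), dt_react)
}

#' Discretized female/male density field
#'
#' @param f,m Numeric vectors of equal length: female and male densities at
#'   the grid nodes. Must be non-negative and satisfy `f + m <= 1` (up to a
#'   small tolerance) pointwise — validated here, at initialization only;
#'   the dynamics keeps biologically initialized states in the simplex
#'   without clipping.
#' @param time Elapsed model time carried with the state.
#' @return An object of class `state_field`.
#' @export
state_field <- function(f, m, time = 0) {
  stopifnot(is.numeric(f), is.numeric(m), length(f) == length(m))
  if (any(f < 0) || any(m < 0)) stop("densities must be non-negative")
  if (any(f + m > 1 + 1e-8))
    stop("f + m must not exceed 1 (occupancy fractions)")
  structure(list(f = as.numeric(f), m = as.numeric(m), time = time),
            class = "state_field")
}

#' @export
print.state_field <- function(x, ...) {
  cat(sprintf(
    "state_field: %d nodes, t = %.6g, mean total density = %.6g, max = %.6g\n",
    length(x$f), x$time, mean(x$f + x$m), max(x$f + x$m)))
  invisible(x)
}

#' Rectangular (uniform-cluster) initial condition
#'
#' Homogeneous female and male clusters of lengths `L_f` and `L_m`, both
#' centered at the habitat midpoint; densities are zero outside. Cluster
#' membership is decided at grid nodes, so lengths are effectively
#' quantized to the grid spacing.
#'
#' Each grid node is treated as a cell of width `dx`; a cluster of length
#' `L` occupies the `round(L/dx)` cells whose centers fall in the
#' half-open interval `[mid - L/2, mid + L/2)`, so the discrete release
#' mass `n * round(L/dx) * dx` equals `n * L` exactly for lattice-aligned
#' lengths and the occupied width grows monotonically, one cell at a time.
#'
#' @param grid A [grid_1d()] object.
#' @param n_f,n_m In-cluster female and male densities.
#' @param L_f Female cluster length.
#' @param L_m Male cluster length; defaults to `L_f`.
#' @return A [state_field()].
#' @export
rectangular_ic <- function(grid, n_f, n_m, L_f, L_m = L_f) {
  stopifnot(inherits(grid, "grid_1d"), n_f >= 0, n_m >= 0, L_f >= 0, L_m >= 0)
  mid <- grid$length / 2
  inside <- function(L)
    grid$x >= mid - L / 2 - 1e-9 * grid$dx & grid$x < mid + L / 2 - 1e-9 * grid$dx
  f <- ifelse(inside(L_f), n_f, 0)
  m <- ifelse(inside(L_m), n_m, 0)
  state_field(f, m)
}
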