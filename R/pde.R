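boundary_code <- function(grid) if (grid$boundary == "no-flux") 0L else 1L

check_state_grid <- function(state, grid) {
  stopifnot(inherits(state, "state_field"), inherits(grid, "grid_1d"))
  if (length(state$f) != grid$n_points)
    stop("state length does not match grid")
}

#' Advance the two-sex system by explicit-Euler steps
#'
#' One (or `n_steps`) forward-Euler steps with the standard 3-point
#' Laplacian stencil. Negative round-off values are clipped to zero.
#'
#' @param state A [state_field()].
#' @param params A [model_params()].
#' @param grid A [grid_1d()].
#' @param cfg An [integration_config()]; its `dt` (or the default bound) is
#'   used.
#' @param n_steps Number of Euler steps to take (default 1).
#' @return The advanced [state_field()].
#' @export
step <- function(state, params, grid, cfg = integration_config(),
                 n_steps = 1) {
  check_state_grid(state, grid)
  stopifnot(inherits(params, "model_params"))
  dt <- resolve_dt(cfg, params, grid)
  res <- pde_run_cpp(state$f, state$m,
                     params$r, params$mu_f, params$mu_m,
                     params$D_f, params$D_m, params$sigma,
                     grid$dx, dt, boundary_code(grid),
                     cfg$tol_converge, Inf, state$time, 0,
                     -1, -1, -1, -1, as.integer(n_steps))
  if (res$status == 3)
    stop("PDE integration diverged (non-finite values); reduce dt")
  state_field(res$f, res$m, time = res$time)
}

classify_outcome <- function(mean_total, status, eq,
                             persistence_band = 0.1, extinct_tol = 1e-4) {
  if (status == 2 || mean_total < extinct_tol) return("EXTINCTION")
  if (status == 4) return("PERSISTENCE")
  if (status == 1) return("NOT_CONVERGED")
  if (eq$exists &&
      abs(mean_total - eq$persistence_total) <=
        persistence_band * eq$persistence_total)
    return("PERSISTENCE")
  "NOT_CONVERGED"
}

#' Integrate the two-sex system to its global equilibrium
#'
#' Steps the explicit-Euler scheme until the maximum absolute
#' time-derivative over the grid drops below `cfg$tol_converge`, then
#' classifies the outcome: `PERSISTENCE` when the final mean total density
#' lies within `persistence_band` (relative) of the persistence-equilibrium
#' total, `EXTINCTION` when it is below `extinct_tol`, `NOT_CONVERGED` when
#' `max_time` is exhausted first. A certified early exit declares
#' extinction as soon as both density fields lie strictly below the Allee
#' equilibrium everywhere (the state is then inside the extinction basin,
#' by comparison with the homogeneous dynamics), which shortens the many
#' sub-critical runs a binary search performs.
#'
#' @inheritParams step
#' @param persistence_band Relative band around the persistence total used
#'   to declare restoration (default 0.1).
#' @param extinct_tol Mean total density below which extinction is declared
#'   (default 1e-4).
#' @param early_exit Use the certified below-Allee extinction exit
#'   (default TRUE).
#' @return A list with `state` (final [state_field()]), `outcome` (list
#'   with `label`, `final_mean_density`, `elapsed_time`, `steps`,
#'   `max_deriv`) and, when `cfg$record_every > 0`, `snapshots` (list of
#'   `time`, `f`, `m` matrices, rows = snapshot times).
#' @export
integrate_to_equilibrium <- function(state, params, grid,
                                     cfg = integration_config(),
                                     persistence_band = 0.1,
                                     extinct_tol = 1e-4,
                                     early_exit = TRUE) {
  check_state_grid(state, grid)
  stopifnot(inherits(params, "model_params"))
  dt <- resolve_dt(cfg, params, grid)
  eq <- equilibria(params)
  f_exit <- m_exit <- f_pers <- m_pers <- -1
  if (early_exit && eq$exists) {
    f_exit <- eq$allee["f"] * 0.999
    m_exit <- eq$allee["m"] * 0.999
    f_pers <- eq$allee["f"] * 1.001
    m_pers <- eq$allee["m"] * 1.001
  }
  res <- pde_run_cpp(state$f, state$m,
                     params$r, params$mu_f, params$mu_m,
                     params$D_f, params$D_m, params$sigma,
                     grid$dx, dt, boundary_code(grid),
                     cfg$tol_converge, cfg$max_time, state$time,
                     cfg$record_every, f_exit, m_exit, f_pers, m_pers, -1L)
  if (res$status == 3)
    stop("PDE integration diverged (non-finite values); reduce dt")
  final <- state_field(res$f, res$m, time = res$time)
  mean_total <- mean(res$f + res$m)
  label <- classify_outcome(mean_total, res$status, eq,
                            persistence_band, extinct_tol)
  out <- list(state = final,
              outcome = list(label = label,
                             final_mean_density = mean_total,
                             elapsed_time = res$time,
                             steps = res$steps,
                             max_deriv = res$max_deriv))
  if (!is.null(res$records)) out$snapshots <- res$records
  out
}

#' Integrate the reduced single-sex equation
#'
#' Scalar analogue of [integrate_to_equilibrium()] for
#' \eqn{\partial_t u = D u_{xx} + (\sigma/2) u^2 (1-2u) - \mu u}. The
#' reaction term is evaluated with the same floating-point operation order
#' as the two-sex kernel at `r = 1/2`, so a symmetric two-sex run and the
#' corresponding single-sex run agree exactly.
#'
#' @param u0 Initial density vector on the grid nodes.
#' @param p A [single_sex_params()].
#' @param grid A [grid_1d()].
#' @param cfg An [integration_config()].
#' @param persistence_band,extinct_tol,early_exit As in
#'   [integrate_to_equilibrium()]; classification compares the mean of `2u`
#'   (both sexes) with the symmetric persistence total `2 u_+`.
#' @return A list with `u` (final density vector), `outcome`, and
#'   optionally `snapshots` (`time`, `u` matrix).
#' @export
run_single_sex <- function(u0, p, grid, cfg = integration_config(),
                           persistence_band = 0.1, extinct_tol = 1e-4,
                           early_exit = TRUE) {
  stopifnot(inherits(p, "single_sex_params"), inherits(grid, "grid_1d"),
            is.numeric(u0), length(u0) == grid$n_points)
  if (any(u0 < 0)) stop("densities must be non-negative")
  dt <- resolve_dt(cfg, p, grid)
  roots <- single_sex_roots(p)
  u_exit <- if (early_exit && roots$exists) roots$u_minus * 0.999 else -1
  u_pers <- if (early_exit && roots$exists) roots$u_minus * 1.001 else -1
  res <- pde_run_single_cpp(u0, p$mu, p$D, p$sigma,
                            grid$dx, dt, boundary_code(grid),
                            cfg$tol_converge, cfg$max_time, 0,
                            cfg$record_every, u_exit, u_pers, -1L)
  if (res$status == 3)
    stop("PDE integration diverged (non-finite values); reduce dt")
  # classify on the total (= 2u) scale so labels match the two-sex runs
  eq <- list(exists = roots$exists,
             persistence_total = if (roots$exists) 2 * roots$u_plus else NA)
  mean_total <- mean(2 * res$u)
  label <- classify_outcome(mean_total, res$status, eq,
                            persistence_band, extinct_tol)
  out <- list(u = res$u,
              outcome = list(label = label,
                             final_mean_density = mean_total,
                             elapsed_time = res$time,
                             steps = res$steps,
                             max_deriv = res$max_deriv))
  if (!is.null(res$records)) out$snapshots <- res$records
  out
}
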