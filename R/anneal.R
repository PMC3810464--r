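#' Discretized release-shape state for annealing
#'
#' A pair of per-node initial density vectors with their release cost
#' `(sum(f) + sum(m)) * dx`. The support (range of nodes where either sex
#' is present) is tracked so shape moves can grow or shrink it.
#'
#' @param f,m Non-negative density vectors on the grid nodes.
#' @param dx Grid spacing used for the cost quadrature.
#' @return An object of class `shape_state` with fields `f`, `m`,
#'   `support` (index range, `c(NA, NA)` when empty), `cost`, `dx`.
#' @export
shape_state <- function(f, m, dx) {
  stopifnot(is.numeric(f), is.numeric(m), length(f) == length(m), dx > 0)
  if (any(f < 0) || any(m < 0)) stop("densities must be non-negative")
  idx <- which(f > 0 | m > 0)
  structure(list(f = as.numeric(f), m = as.numeric(m),
                 support = if (length(idx)) range(idx) else c(NA, NA),
                 cost = (sum(f) + sum(m)) * dx, dx = dx),
            class = "shape_state")
}

#' @export
print.shape_state <- function(x, ...) {
  cat(sprintf("shape_state: %d nodes, support [%s, %s], cost %.6g\n",
              length(x$f), x$support[1], x$support[2], x$cost))
  invisible(x)
}

#' Annealing schedule and move configuration
#'
#' @param T0 Initial temperature-like parameter. `NULL` (default) sets it
#'   at run time to the standard deviation of cost changes over 100 random
#'   feasible proposals from the initial state.
#' @param cooling Geometric cooling factor per stage, in (0, 1).
#' @param moves_per_stage Proposals per temperature stage.
#' @param move_amplitude Maximum single-site density perturbation. `NULL`
#'   defaults to 20% of the mean persistence-equilibrium per-sex density.
#' @param seed RNG seed (`NULL` = leave the RNG state alone).
#' @param max_stages Cap on cooling stages.
#' @param min_accept_rate Stop when a stage's acceptance rate falls below
#'   this (default 0.01).
#' @param p_moves Probabilities of the three move kinds: perturb a site,
#'   grow the support by one edge cell, shrink it by one edge cell.
#' @param infeasible_policy Only `"reject"` is implemented: proposals whose
#'   PDE run fails restoration are rejected outright, keeping the chain in
#'   the feasible region.
#' @return An object of class `anneal_config`.
#' @export
anneal_config <- function(T0 = NULL, cooling = 0.95, moves_per_stage = 200,
                          move_amplitude = NULL, seed = NULL,
                          max_stages = 50, min_accept_rate = 0.01,
                          p_moves = c(perturb = 0.8, grow = 0.1, shrink = 0.1),
                          infeasible_policy = "reject") {
  stopifnot(cooling > 0, cooling < 1, moves_per_stage >= 1,
            length(p_moves) == 3, all(p_moves >= 0), sum(p_moves) > 0,
            identical(infeasible_policy, "reject"))
  structure(list(T0 = T0, cooling = cooling,
                 moves_per_stage = as.integer(moves_per_stage),
                 move_amplitude = move_amplitude, seed = seed,
                 max_stages = as.integer(max_stages),
                 min_accept_rate = min_accept_rate,
                 p_moves = p_moves / sum(p_moves),
                 infeasible_policy = infeasible_policy),
            class = "anneal_config")
}

#' Propose a random shape change
#'
#' One elementary annealing move: with the configured probabilities either
#' perturb a uniformly chosen occupied site of a uniformly chosen sex by
#' `uniform(-a, +a)` (clipped at zero), extend that sex's support by one
#' cell at a random edge with a small seed density (`uniform(0, a)`), or
#' zero out a random edge cell. Uses R's RNG stream.
#'
#' @param state A [shape_state()].
#' @param amplitude Maximum density perturbation `a`.
#' @param p_moves Length-3 probabilities (perturb, grow, shrink).
#' @return The proposed [shape_state()].
#' @export
propose_shape <- function(state, amplitude,
                          p_moves = c(0.8, 0.1, 0.1)) {
  stopifnot(inherits(state, "shape_state"), amplitude >= 0)
  if (amplitude == 0) return(state)
  f <- state$f; m <- state$m; n <- length(f)
  sex <- if (stats::runif(1) < 0.5) "f" else "m"
  v <- if (sex == "f") f else m
  other <- if (sex == "f") m else f
  occ <- which(v > 0)
  kind <- sample.int(3, 1, prob = p_moves)
  if (kind == 1 && length(occ)) {          # perturb an occupied site
    i <- occ[sample.int(length(occ), 1)]
    # clip into the occupancy simplex f + m <= 1
    v[i] <- min(max(0, v[i] + stats::runif(1, -amplitude, amplitude)),
                1 - other[i])
  } else if (kind == 2) {                  # grow support by one edge cell
    if (length(occ)) {
      edge <- if (stats::runif(1) < 0.5) min(occ) - 1L else max(occ) + 1L
    } else edge <- sample.int(n, 1)
    if (edge >= 1 && edge <= n)
      v[edge] <- min(stats::runif(1, 0, amplitude), 1 - other[edge])
  } else if (length(occ)) {                # shrink: zero out an edge cell
    edge <- if (stats::runif(1) < 0.5) min(occ) else max(occ)
    v[edge] <- 0
  }
  if (sex == "f") f <- v else m <- v
  shape_state(f, m, state$dx)
}

#' Restoration feasibility of a release shape
#'
#' Injects the shape as the PDE initial condition and integrates to the
#' global equilibrium: feasible means the outcome is `PERSISTENCE`.
#' `NOT_CONVERGED` runs count as infeasible, with a warning.
#'
#' @param state A [shape_state()].
#' @param params A [model_params()].
#' @param grid A [grid_1d()] whose spacing matches `state$dx`.
#' @param cfg An [integration_config()].
#' @return Logical.
#' @export
feasible <- function(state, params, grid, cfg = integration_config()) {
  stopifnot(inherits(state, "shape_state"))
  res <- integrate_to_equilibrium(state_field(state$f, state$m),
                                  params, grid, cfg)
  if (res$outcome$label == "NOT_CONVERGED")
    warning("feasibility run did not converge; treated as infeasible")
  res$outcome$label == "PERSISTENCE"
}

#' Simulated annealing over release shapes
#'
#' Metropolis Monte-Carlo minimization of the release cost over
#' discretized sex-specific initial density shapes, constrained to shapes
#' whose PDE integration restores the population. Cost-increasing
#' proposals are accepted with probability `exp(-dC/T)`; accepted
#' proposals are additionally screened by a full PDE feasibility run
#' (infeasible ones are rejected outright, so the chain never leaves the
#' feasible region). The temperature is cooled geometrically per stage;
#' annealing stops when the acceptance rate collapses or `max_stages` is
#' reached. The best feasible state ever visited is returned and is
#' re-verified with a fresh integration.
#'
#' @param params A [model_params()].
#' @param grid A [grid_1d()].
#' @param cfg An [anneal_config()].
#' @param init A feasible [shape_state()] (an error is raised otherwise).
#' @param pde_cfg An [integration_config()] for the feasibility runs.
#' @return A list with `state` (best feasible [shape_state()]), `cost`,
#'   `trace` (per-stage data.frame: stage, temperature, current and best
#'   cost, acceptance rate, PDE evaluations), and `diagnostics`.
#' @export
anneal <- function(params, grid, cfg = anneal_config(), init,
                   pde_cfg = integration_config()) {
  stopifnot(inherits(cfg, "anneal_config"), inherits(init, "shape_state"),
            inherits(grid, "grid_1d"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (abs(init$dx - grid$dx) > 1e-9 * grid$dx)
    stop("shape dx does not match grid dx")
  pde_evals <- 0L
  check <- function(st) {
    pde_evals <<- pde_evals + 1L
    feasible(st, params, grid, pde_cfg)
  }
  if (!check(init)) stop("initial shape is not feasible")

  eq <- equilibria(params)
  amplitude <- cfg$move_amplitude
  if (is.null(amplitude))
    amplitude <- 0.2 * eq$persistence_total / 2

  T0 <- cfg$T0
  if (is.null(T0)) {
    dC <- numeric(0)
    for (i in 1:100) {
      prop <- propose_shape(init, amplitude, cfg$p_moves)
      if (abs(prop$cost - init$cost) < 1e-15) next
      if (check(prop)) dC <- c(dC, prop$cost - init$cost)
    }
    T0 <- stats::sd(dC)
    if (!is.finite(T0) || T0 <= 0) T0 <- amplitude * grid$dx
  }

  cur <- init; best <- init
  Temp <- T0
  trace <- NULL
  for (stage in seq_len(cfg$max_stages)) {
    accepted <- 0L
    for (k in seq_len(cfg$moves_per_stage)) {
      prop <- propose_shape(cur, amplitude, cfg$p_moves)
      dC <- prop$cost - cur$cost
      metro <- dC <= 0 || stats::runif(1) < exp(-dC / Temp)
      if (!metro) next
      if (!check(prop)) next   # infeasible: rejected outright
      cur <- prop
      accepted <- accepted + 1L
      if (cur$cost < best$cost) best <- cur
    }
    rate <- accepted / cfg$moves_per_stage
    trace <- rbind(trace, data.frame(
      stage = stage, temperature = Temp, current_cost = cur$cost,
      best_cost = best$cost, accept_rate = rate, pde_evals = pde_evals))
    if (rate < cfg$min_accept_rate) break
    Temp <- Temp * cfg$cooling
  }
  if (!check(best)) # re-verify the reported optimum on a fresh run
    warning("best visited state failed the feasibility re-check")
  list(state = best, cost = best$cost, trace = trace,
       diagnostics = list(T0 = T0, amplitude = amplitude,
                          stages = nrow(trace), pde_evals = pde_evals,
                          seed = cfg$seed))
}
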