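#' Cost of a rectangular release design
#'
#' With constant per-capitum cost, the cost of homogeneous clusters is the
#' number of individuals released: `n_f * L_f + n_m * L_m`.
#'
#' @param n_f,n_m In-cluster female and male densities.
#' @param L_f,L_m Cluster lengths; `L_m` defaults to `L_f`.
#' @return The release cost (individuals, in density x length units).
#' @examples
#' cost_rectangular(0.3, 0.3, 10)  # 6
#' @export
cost_rectangular <- function(n_f, n_m, L_f, L_m = L_f) {
  stopifnot(all(n_f >= 0), all(n_m >= 0), all(L_f >= 0), all(L_m >= 0))
  n_f * L_f + n_m * L_m
}

divergent_error <- function(msg) {
  stop(structure(class = c("reintro_divergent", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Test for the divergence condition signalled by critical searches
#' @param x An object, typically caught with `tryCatch`.
#' @return Logical.
#' @export
is_divergent <- function(x) inherits(x, "reintro_divergent")

new_critical_result <- function(value, bracket, evaluations, what, extra = list()) {
  structure(c(list(value = value, bracket = bracket,
                   evaluations = evaluations, what = what), extra),
            class = "critical_result")
}

#' @export
print.critical_result <- function(x, ...) {
  cat(sprintf("Critical %s: %.6g  (bracket [%.6g, %.6g], %d PDE runs)\n",
              x$what, x$value, x$bracket[1], x$bracket[2], x$evaluations))
  invisible(x)
}

# Shared machinery: monotone outcome assumed in the search variable;
# classify() must return TRUE (persistence) / FALSE.
bisect_threshold <- function(classify, lo, hi, resolution) {
  evals <- 0L
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    ok <- classify(mid)
    evals <- evals + 1L
    if (ok) hi <- mid else lo <- mid
  }
  list(lo = lo, hi = hi, evals = evals)
}

# Integer-cell bisection: lengths are lattice multiples of dx so the
# discretized cluster grows by exactly one cell per unit. classify takes
# the cell count; k_lo is known infeasible (or 0), k_hi known feasible.
bisect_cells <- function(classify, k_lo, k_hi, min_gap = 1L) {
  evals <- 0L
  while (k_hi - k_lo > min_gap) {
    k <- (k_lo + k_hi) %/% 2
    ok <- classify(k)
    evals <- evals + 1L
    if (ok) k_hi <- k else k_lo <- k
  }
  list(k_lo = k_lo, k_hi = k_hi, evals = evals)
}

make_search_grid <- function(length, dx, boundary = "no-flux") {
  n <- max(16L, as.integer(round(length / dx)) + 1L)
  grid_1d(length = (n - 1L) * dx, n_points = n, boundary = boundary)
}

#' Critical cluster length for a rectangular release
#'
#' Finds, by binary search on the common cluster length `L_f = L_m = L`,
#' the smallest length at which a rectangular release at densities
#' `(n_f, n_m)` leads to restoration rather than extinction, classifying
#' each candidate with a full PDE integration. The habitat is auto-sized to
#' `habitat_factor` times the current search upper bound (no-flux
#' boundaries stay inert); an initial doubling phase brackets the
#' threshold, then bisection narrows it to `resolution`.
#'
#' @param params A [model_params()] object; must admit positive equilibria.
#' @param n_f,n_m Release densities; default to the persistence-equilibrium
#'   densities. Must exceed the Allee equilibrium componentwise.
#' @param resolution Width of the final bracket; defaults to `dx`.
#' @param dx Grid spacing (also the length quantum); default 0.25.
#' @param L_max Upper search bound; default `50 * sqrt(max(D) / min(mu))`.
#'   If that length still goes extinct the search signals a divergence
#'   error (class `reintro_divergent`): sub-threshold densities or the
#'   non-spreading regime.
#' @param habitat_factor Habitat length as a multiple of the search upper
#'   bound (default 6).
#' @param cfg An [integration_config()] shared by all runs.
#' @return A `critical_result`: `value` (bracket midpoint), `bracket`
#'   (`c(lo, hi)`; `hi` is the smallest tested length that persists),
#'   `evaluations`, plus the densities and grid used.
#' @export
critical_length <- function(params, n_f = NULL, n_m = NULL,
                            resolution = NULL, dx = 0.25,
                            L_max = NULL, habitat_factor = 6,
                            cfg = integration_config()) {
  stopifnot(inherits(params, "model_params"))
  eq <- equilibria(params)
  if (!eq$exists)
    divergent_error("no positive equilibria: restoration impossible")
  if (is.null(n_f)) n_f <- unname(eq$persistence["f"])
  if (is.null(n_m)) n_m <- unname(eq$persistence["m"])
  if (is.null(resolution)) resolution <- dx
  if (n_f <= eq$allee["f"] || n_m <= eq$allee["m"])
    divergent_error("release densities do not exceed the Allee equilibrium")
  maxD <- max(params$D_f, params$D_m, 1e-12)
  if (is.null(L_max)) L_max <- 50 * sqrt(maxD / min(params$mu_f, params$mu_m))

  evals <- 0L
  classify_on <- function(k, grid) {
    st <- rectangular_ic(grid, n_f, n_m, k * dx, k * dx)
    evals <<- evals + 1L
    res <- integrate_to_equilibrium(st, params, grid, cfg)
    if (res$outcome$label == "NOT_CONVERGED")
      warning("PDE run did not converge within max_time; treated as failure")
    res$outcome$label == "PERSISTENCE"
  }
  # bracket by doubling on the cell lattice, habitat re-sized per candidate
  k <- max(4L, as.integer(ceiling(sqrt(maxD / max(params$mu_f, params$mu_m)) / dx)))
  while (!classify_on(k, make_search_grid(habitat_factor * k * dx, dx))) {
    k <- 2L * k
    if (k * dx > L_max)
      divergent_error(sprintf(
        "no persistence up to L_max = %.4g: non-spreading regime or densities too low",
        L_max))
  }
  # fixed habitat for the bisection phase
  grid <- make_search_grid(habitat_factor * k * dx, dx)
  if (!classify_on(k, grid)) k <- 2L * k
  min_gap <- max(1L, as.integer(round(resolution / dx)))
  b <- bisect_cells(function(kk) classify_on(kk, grid), 0L, k, min_gap)
  new_critical_result((b$k_lo + b$k_hi) / 2 * dx,
                      c(b$k_lo, b$k_hi) * dx, evals, "length",
                      list(n_f = n_f, n_m = n_m, grid = grid, dx = dx,
                           k_crit = b$k_hi))
}

#' Critical release density at fixed cluster length
#'
#' Binary search on the total in-cluster density at a fixed common cluster
#' length `L`, splitting the total between the sexes in a fixed proportion
#' (default: the persistence-equilibrium proportion).
#'
#' @inheritParams critical_length
#' @param L Common cluster length (> 0).
#' @param resolution Final bracket width on the total-density axis.
#' @param split_f Fraction of the total density assigned to females;
#'   default `f* / (f* + m*)`.
#' @return A `critical_result` with `value` = critical total density.
#'   Signals a divergence error when even the saturated density
#'   (`f + m = 1`) fails: `L` is below the minimal nucleus width.
#' @export
critical_density <- function(params, L, resolution = 1e-3, split_f = NULL,
                             dx = 0.25, habitat_factor = 6,
                             cfg = integration_config()) {
  stopifnot(inherits(params, "model_params"), L > 0)
  eq <- equilibria(params)
  if (!eq$exists)
    divergent_error("no positive equilibria: restoration impossible")
  if (is.null(split_f)) split_f <- eq$persistence["f"] / eq$persistence_total
  grid <- make_search_grid(habitat_factor * max(L, 4 * sqrt(
    max(params$D_f, params$D_m, 1e-12) / min(params$mu_f, params$mu_m))), dx)
  evals <- 0L
  classify <- function(n_tot) {
    st <- rectangular_ic(grid, split_f * n_tot, (1 - split_f) * n_tot, L, L)
    evals <<- evals + 1L
    res <- integrate_to_equilibrium(st, params, grid, cfg)
    res$outcome$label == "PERSISTENCE"
  }
  if (!classify(1))
    divergent_error("even saturated density fails: L below the minimal nucleus width")
  b <- bisect_threshold(classify, eq$allee_total, 1, resolution)
  new_critical_result((b$lo + b$hi) / 2, c(b$lo, b$hi), evals, "density",
                      list(L = L, split_f = unname(split_f), grid = grid))
}

#' Scaling exponent of the critical length in the diffusion coefficient
#'
#' Runs [critical_length()] over a set of diffusion coefficients (scaling
#' both sexes together, or one sex with the other fixed) and returns the
#' least-squares slope of `log(critical length)` against `log(D)`. The
#' continuum rescaling symmetry `x -> sqrt(c) x` predicts a slope of 1/2
#' when both coefficients scale together.
#'
#' @param params A [model_params()] whose `D_f`, `D_m` serve as the base
#'   coefficients.
#' @param D_values Diffusion multipliers/values (>= 4 values spanning at
#'   least a decade recommended).
#' @param vary `"both"` (scale `D_f` and `D_m` by each value) or `"male"`
#'   (set `D_m` to each value, `D_f` fixed).
#' @param n_f,n_m Fixed release densities (defaults: persistence
#'   equilibria of `params`).
#' @param ... Passed to [critical_length()] (`dx`, `resolution`, `cfg`...).
#' @return List with `exponent`, `fit` (the `lm`), and `table`
#'   (data.frame of `D`, `critical_length`).
#' @export
scaling_exponent <- function(params, D_values, vary = c("both", "male"),
                             n_f = NULL, n_m = NULL, ...) {
  vary <- match.arg(vary)
  stopifnot(length(D_values) >= 2, all(D_values > 0))
  eq <- equilibria(params)
  if (is.null(n_f)) n_f <- unname(eq$persistence["f"])
  if (is.null(n_m)) n_m <- unname(eq$persistence["m"])
  L <- vapply(D_values, function(D) {
    pp <- if (vary == "both")
      model_params(params$r, params$mu_f, params$mu_m,
                   D_f = params$D_f * D, D_m = params$D_m * D, params$sigma)
    else
      model_params(params$r, params$mu_f, params$mu_m,
                   D_f = params$D_f, D_m = D, params$sigma)
    critical_length(pp, n_f = n_f, n_m = n_m, ...)$value
  }, numeric(1))
  tab <- data.frame(D = D_values, critical_length = L)
  fit <- stats::lm(log(critical_length) ~ log(D), data = tab)
  list(exponent = unname(stats::coef(fit)[2]), fit = fit, table = tab)
}

#' Cost of assured restoration as a function of release density
#'
#' For each total density (split equally between the sexes unless
#' `split_f` is given), finds the critical cluster length and the cost
#' `n_tot * L_c`. The critical length diverges as the density approaches
#' the Allee total from above; the cost minimum sits slightly below the
#' persistence-equilibrium total.
#'
#' @inheritParams critical_length
#' @param density_grid Total densities to scan (must exceed the Allee
#'   total).
#' @param split_f Female share of the total density (default 1/2).
#' @param ... Passed to [critical_length()].
#' @return A data.frame `(density, critical_length, cost)` with attributes
#'   `argmin` (row index of the cost minimum) and `persistence_total`.
#' @export
cost_vs_density_scan <- function(params, density_grid, split_f = 0.5, ...) {
  eq <- equilibria(params)
  if (!eq$exists)
    divergent_error("no positive equilibria: restoration impossible")
  res <- lapply(density_grid, function(n_tot) {
    cl <- critical_length(params, n_f = split_f * n_tot,
                          n_m = (1 - split_f) * n_tot, ...)
    data.frame(density = n_tot, critical_length = cl$value,
               cost = n_tot * cl$value)
  })
  out <- do.call(rbind, res)
  attr(out, "argmin") <- which.min(out$cost)
  attr(out, "persistence_total") <- eq$persistence_total
  out
}

#' Cost of assured restoration as a function of birth sex ratio
#'
#' Scans the sex ratio at birth over `r_grid`; for each `r` the release
#' densities are set to the `r`-dependent persistence-equilibrium
#' densities, the equal-cluster critical length is found by binary search,
#' and the cost is `(f* + m*) * L_c`. The cost-minimizing `r` carries a
#' numerical error band: the range of scanned `r` whose critical lengths
#' lie within one binary-search bracket width of the minimum.
#'
#' @param mu_f,mu_m Mortality rates.
#' @param D_f,D_m Diffusion coefficients.
#' @param r_grid Sex ratios to scan (within the admissible band).
#' @param sigma Birth-rate scale.
#' @param ... Passed to [critical_length()].
#' @return A data.frame `(r, critical_length, cost, n_f, n_m)` with
#'   attributes `r_min` (cost-minimizing scanned `r`), `r_band`
#'   (`c(lo, hi)` error band) and `r_star`
#'   (= [optimal_sex_ratio()]). Scanned values outside the admissible
#'   band, or failing to restore, are dropped with a warning.
#' @export
cost_vs_sex_ratio_scan <- function(mu_f, mu_m, D_f, D_m, r_grid,
                                   sigma = 1, ...) {
  rows <- lapply(r_grid, function(r) {
    pp <- try(model_params(r, mu_f, mu_m, D_f, D_m, sigma), silent = TRUE)
    if (inherits(pp, "try-error") || !stability_condition_two_sex(pp))
      return(NULL)
    eq <- equilibria(pp)
    cl <- tryCatch(critical_length(pp, ...),
                   reintro_divergent = function(e) NULL)
    if (is.null(cl)) return(NULL)
    data.frame(r = r, critical_length = cl$value,
               cost = eq$persistence_total * cl$value,
               n_f = unname(eq$persistence["f"]),
               n_m = unname(eq$persistence["m"]),
               bracket_width = diff(cl$bracket))
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped > 0)
    warning(sprintf("%d sex-ratio value(s) dropped (inadmissible or divergent)",
                    dropped))
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no admissible sex-ratio values in r_grid")
  i_min <- which.min(out$cost)
  # error band: r values whose critical length is within the binary-search
  # error of the minimum point's critical length
  in_band <- out$critical_length <=
    out$critical_length[which.min(out$critical_length)] + out$bracket_width
  attr(out, "r_min") <- out$r[i_min]
  attr(out, "r_band") <- range(out$r[in_band])
  attr(out, "r_star") <- optimal_sex_ratio(mu_f, mu_m)
  out
}
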