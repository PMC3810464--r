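#' Growth potential of the single-sex dynamics
#'
#' Antiderivative \eqn{G(u) = \int_0^u g(v)\,dv
#'   = \sigma u^3/6 - \sigma u^4/4 - \mu u^2/2}
#' of the cubic growth law, normalized so \eqn{G(0) = 0}. Stationary
#' profiles of the PDE conserve \eqn{E = (D/2)(u')^2 + G(u)}, so `G` plays
#' the role of a potential for the spatial phase plane: the local equilibria
#' \eqn{u_\pm} are its critical points.
#'
#' @param u Density; vectorized.
#' @param p A [single_sex_params()].
#' @return Numeric vector of potential values.
#' @export
allee_potential <- function(u, p) {
  stopifnot(inherits(p, "single_sex_params"))
  p$sigma * u^3 / 6 - p$sigma * u^4 / 4 - p$mu * u^2 / 2
}

#' First integral of the stationary equation
#'
#' For the stationary problem \eqn{D u'' + g(u) = 0}, the quantity
#' \eqn{E = (D/2)(du/dx)^2 + G(u)} is conserved along any solution and
#' labels the orbit families of the spatial phase plane.
#'
#' @param u Density.
#' @param du_dx Spatial derivative of the density.
#' @param p A [single_sex_params()].
#' @return The first-integral value `E`.
#' @export
first_integral <- function(u, du_dx, p) {
  stopifnot(inherits(p, "single_sex_params"))
  p$D / 2 * du_dx^2 + allee_potential(u, p)
}

#' Separatrix first-integral values and fixed-point classification
#'
#' In the bistable regime the spatial phase plane has three fixed points on
#' the `du/dx = 0` axis: the extinction state `u = 0` and the carrying
#' density `u_+` (both saddles of the spatial system — they are the stable
#' nodes of the local dynamics) and the Allee threshold `u_-` (a center —
#' the unstable local equilibrium). The separatrices through the saddles
#' carry first-integral values `G(0) = 0` and `G(u_+)`; periodic orbits
#' fill the band between `G(u_-)` (the potential minimum at the center) and
#' the lower saddle value.
#'
#' @param p A [single_sex_params()] in the bistable regime
#'   (`mu < sigma/16`).
#' @return List with `E_extinction`, `E_persistence`, `E_center`,
#'   `u_minus`, `u_plus`, and `classification` (named character vector:
#'   "saddle"/"center" from the linearization eigenvalues
#'   \eqn{\pm\sqrt{-g'(u^*)/D}}).
#' @export
separatrix_constants <- function(p) {
  stopifnot(inherits(p, "single_sex_params"))
  roots <- single_sex_roots(p)
  if (!roots$exists)
    stop("no bistable regime: requires mu < sigma/16")
  classify <- function(u) {
    gp <- single_sex_rate_deriv(u, p)
    if (gp < 0) "saddle" else "center"  # eigenvalues +/- sqrt(-g'(u)/D)
  }
  list(E_extinction = allee_potential(0, p),
       E_persistence = allee_potential(roots$u_plus, p),
       E_center = allee_potential(roots$u_minus, p),
       u_minus = roots$u_minus, u_plus = roots$u_plus,
       classification = c(extinction = classify(0),
                          center = classify(roots$u_minus),
                          persistence = classify(roots$u_plus)))
}

#' Spatial period of a periodic stationary orbit
#'
#' Periodic stationary solutions encircle the center `u_-` for
#' first-integral values `E` strictly between `G(u_-)` and the lower
#' saddle value `min(G(0), G(u_+))`. The period is the closed-orbit
#' quadrature
#' \deqn{\Lambda(E) = 2 \int_{u_1}^{u_2} \frac{du}{\sqrt{(2/D)(E - G(u))}},}
#' between the turning points `u_1 < u_- < u_2` (roots of `G(u) = E`).
#' As the amplitude vanishes the period tends to the harmonic limit
#' \eqn{2\pi\sqrt{D/g'(u_-)}} — not to zero — and it diverges as `E`
#' approaches the separatrix.
#'
#' @param E First-integral value inside the periodic band.
#' @param p A [single_sex_params()] in the bistable regime.
#' @return The spatial period (length units).
#' @export
orbit_period <- function(E, p) {
  sep <- separatrix_constants(p)
  E_lo <- sep$E_center
  E_hi <- min(sep$E_extinction, sep$E_persistence)
  if (E <= E_lo || E >= E_hi)
    stop("E is outside the periodic band (G(u_-), min(G(0), G(u_+)))")
  a <- sep$u_minus
  # stable evaluation of E - G(u): G(u) - G(a) has a double root at the
  # center a (G'(a) = g(a) = 0), so factor it as (u - a)^2 q(u) by two
  # synthetic divisions; this avoids catastrophic cancellation for orbits
  # of tiny amplitude.
  cf <- c(-p$sigma / 4, p$sigma / 6, -p$mu / 2, 0,
          -allee_potential(a, p))      # G(u) - G(a), descending powers
  div_once <- function(cf, a) {
    out <- numeric(length(cf) - 1L)
    out[1] <- cf[1]
    for (i in 2:length(out)) out[i] <- cf[i] + out[i - 1] * a
    out
  }
  q_cf <- div_once(div_once(cf, a), a)   # quadratic q(u)
  q <- function(u) (q_cf[1] * u + q_cf[2]) * u + q_cf[3]
  dE <- E - allee_potential(a, p)        # > 0 inside the band
  # Two evaluation regimes for E - G(u): small-amplitude orbits use the
  # factored form (stable near the center's double root); wide orbits near
  # the separatrix use the direct polynomial (stable near u = 0 where the
  # factored form cancels).
  near_center <- dE < 0.5 * (E_hi - E_lo)
  Wdu <- if (near_center) {
    function(du) (dE - du^2 * q(a + du)) * 2 / p$D  # = (2/D)(E - G(u))
  } else {
    function(du) (E - allee_potential(a + du, p)) * 2 / p$D
  }
  h <- if (near_center) function(u) dE - (u - a)^2 * q(u)
       else function(u) E - allee_potential(u, p)
  u1 <- if (near_center) {
    stats::uniroot(h, c(1e-300, a), tol = 1e-15)$root
  } else {
    # the lower turning point can be exponentially small near the
    # separatrix: root-find on the log scale for relative accuracy
    exp(stats::uniroot(function(v) h(exp(v)), c(log(1e-300), log(a)),
                       tol = 1e-13)$root)
  }
  u2 <- stats::uniroot(h, c(a, sep$u_plus), tol = 1e-15)$root
  d1 <- a - u1; d2 <- u2 - a
  # split at the center; substitute u = u_turn +/- t^2 so the integrand is
  # finite at the turning points
  right <- stats::integrate(function(t) {
    w <- Wdu(d2 - t^2); 2 * t / sqrt(pmax(w, 1e-300))
  }, 0, sqrt(d2), rel.tol = 1e-9, subdivisions = 1000L)$value
  left <- if (near_center) {
    stats::integrate(function(t) {
      w <- Wdu(t^2 - d1); 2 * t / sqrt(pmax(w, 1e-300))
    }, 0, sqrt(d1), rel.tol = 1e-9, subdivisions = 1000L)$value
  } else {
    # Wide orbits skirt the extinction saddle at u = 0, where the passage
    # length diverges logarithmically in the separatrix distance. The
    # substitution u = u1 cosh(s) makes that explicit: with
    # rho(u) = 2 (E - G(u)) / (mu (u^2 - u1^2)) -> 1 near the saddle,
    # the integrand sqrt(D/mu)/sqrt(rho) is smooth and order-1 in s.
    # stable power differences: with c = cosh(s) - 1 = 2 sinh(s/2)^2,
    # (u^n - u1^n)/(u^2 - u1^2) is evaluated via expm1/log1p, and
    # E - G(u) = mu/2 (u^2-u1^2) - sigma/6 (u^3-u1^3) + sigma/4 (u^4-u1^4)
    # (using E = G(u1)), giving rho -> 1 at the saddle without cancellation
    stats::integrate(function(s) {
      cm1 <- 2 * sinh(s / 2)^2
      r2 <- cm1 * (2 + cm1)                       # (1+c)^2 - 1
      r3 <- expm1(3 * log1p(cm1)) / r2
      r4 <- expm1(4 * log1p(cm1)) / r2
      rho <- 1 - (p$sigma / (3 * p$mu)) * u1 * r3 +
        (p$sigma / (2 * p$mu)) * u1^2 * r4
      sqrt(p$D / p$mu) / sqrt(pmax(rho, 1e-300))
    }, 0, acosh(a / u1), rel.tol = 1e-9, subdivisions = 1000L)$value
  }
  2 * (left + right)
}

#' Aperiodic unstable stationary profile (critical nucleus)
#'
#' Constructs the homoclinic stationary solution of the single-sex model:
#' the spatially localized unstable profile on the `E = 0` separatrix that
#' separates shrinking from growing initial populations. It exists in the
#' spreading regime `G(u_+) > 0` (beyond the Maxwell point); its peak
#' density `u_max` is the positive root of `G` between `u_-` and `u_+`.
#' The profile is integrated outward from the peak (series expansion at
#' the peak, where the phase-plane square root degenerates, then
#' high-accuracy ODE integration of `(u, u')`), truncated at a small
#' density `threshold`, mirrored, and returned on a uniform grid of
#' spacing `dx` centered on the peak so it can be injected directly as a
#' PDE initial condition.
#'
#' The release cost is twice the trapezoid area under the truncated curve
#' (both sexes carry the same profile). `cost_with_tail` adds the
#' analytic estimate `4 * threshold * sqrt(D/mu)` of the two discarded
#' exponential tails.
#'
#' @param p A [single_sex_params()] in the spreading regime.
#' @param threshold Truncation density for the tails (default 1e-3).
#' @param dx Output grid spacing.
#' @return An object of class `stationary_profile`: list with `x`
#'   (coordinates centered on the peak), `u`, `u_max`, `threshold`, `E`
#'   (= 0), `cost`, `cost_with_tail`, and the parameters used.
#' @export
aperiodic_profile <- function(p, threshold = 1e-3, dx = 0.05) {
  stopifnot(inherits(p, "single_sex_params"), threshold > 0, dx > 0)
  roots <- single_sex_roots(p)
  if (!roots$exists) stop("no bistable regime: requires mu < sigma/16")
  G <- function(u) allee_potential(u, p)
  if (G(roots$u_plus) <= 0)
    stop("no homoclinic orbit: G(u_plus) <= 0 (non-spreading regime)")
  # peak density: bisection for the zero of G on (u_minus, u_plus)
  lo <- roots$u_minus; hi <- roots$u_plus
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (G(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-14) break
  }
  u_max <- (lo + hi) / 2
  if (threshold >= u_max) stop("threshold must be below the peak density")

  g <- function(u) single_sex_rate(u, p)
  gp <- function(u) single_sex_rate_deriv(u, p)
  # series about the peak: u = u_max + a2 x^2 + a4 x^4 (u'(0) = 0)
  a2 <- -g(u_max) / (2 * p$D)
  a4 <- -gp(u_max) * a2 / (12 * p$D)
  x0 <- min(dx, 1e-3) / 10
  y0 <- c(u = u_max + a2 * x0^2 + a4 * x0^4,
          w = 2 * a2 * x0 + 4 * a4 * x0^3)
  # generous bound on the half-width: core plus exponential tail
  x_end <- (log(u_max / threshold) + 12) * sqrt(p$D / p$mu) + 10 * dx
  times <- unique(c(x0, seq(dx, x_end, by = dx)))
  rhs <- function(x, y, parms) list(c(y["w"], -g(max(y["u"], 0)) / p$D))
  sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsodar", rtol = 1e-12, atol = 1e-12,
                      rootfunc = function(x, y, parms) y["u"] - threshold)
  xs <- sol[, "time"]; us <- sol[, "u"]
  keep <- us >= threshold & abs(xs / dx - round(xs / dx)) < 1e-8 & xs >= dx / 2
  x_half <- xs[keep]; u_half <- us[keep]
  x_full <- c(-rev(x_half), 0, x_half)
  u_full <- c(rev(u_half), u_max, u_half)
  area <- sum((u_full[-1] + u_full[-length(u_full)]) / 2) * dx
  structure(list(x = x_full, u = u_full, u_max = u_max,
                 threshold = threshold, E = 0,
                 cost = 2 * area,
                 cost_with_tail = 2 * area + 4 * threshold * sqrt(p$D / p$mu),
                 dx = dx, params = p),
            class = "stationary_profile")
}

#' @export
print.stationary_profile <- function(x, ...) {
  cat(sprintf(
    "Aperiodic stationary profile: peak %.6g, half-width %.6g, cost %.6g\n",
    x$u_max, max(x$x), x$cost))
  invisible(x)
}

#' Finite-difference residual of a stationary profile
#'
#' Evaluates `D u'' + g(u)` on the interior of a profile with a central
#' finite-difference second derivative (2nd- or 4th-order stencil) and
#' returns the maximum absolute residual. For the exact homoclinic
#' solution this measures only the discretization error of the stencil.
#'
#' @param profile A [aperiodic_profile()] result.
#' @param p A [single_sex_params()]; defaults to the profile's own.
#' @param order Stencil order, 2 or 4.
#' @return Maximum absolute residual over interior nodes.
#' @export
stationary_residual <- function(profile, p = profile$params, order = 4) {
  stopifnot(inherits(profile, "stationary_profile"), order %in% c(2, 4))
  u <- profile$u; dx <- profile$dx; n <- length(u)
  if (order == 2) {
    upp <- (u[1:(n - 2)] - 2 * u[2:(n - 1)] + u[3:n]) / dx^2
    core <- 2:(n - 1)
  } else {
    upp <- (-u[1:(n - 4)] + 16 * u[2:(n - 3)] - 30 * u[3:(n - 2)] +
              16 * u[4:(n - 1)] - u[5:n]) / (12 * dx^2)
    core <- 3:(n - 2)
  }
  max(abs(p$D * upp + single_sex_rate(u[core], p)))
}

#' Place a stationary profile on a habitat grid
#'
#' Interpolates the (peak-centered) profile onto the nodes of a habitat
#' grid, centered at the habitat midpoint, zero outside the truncated
#' support. Linear interpolation is used; with `profile$dx` equal to the
#' grid spacing the node values are carried over unchanged.
#'
#' @param profile A [aperiodic_profile()] result.
#' @param grid A [grid_1d()].
#' @param scale Multiplicative factor applied to the densities (e.g. 1.01
#'   to nudge the critical profile into the restoration basin).
#' @return Numeric vector of densities on the grid nodes (one sex; use
#'   `state_field(u, u)` for the symmetric two-sex state).
#' @export
profile_on_grid <- function(profile, grid, scale = 1) {
  stopifnot(inherits(profile, "stationary_profile"), inherits(grid, "grid_1d"))
  xc <- grid$x - grid$length / 2
  u <- stats::approx(profile$x, profile$u, xout = xc, yleft = 0,
                     yright = 0)$y
  u[abs(xc) > max(profile$x)] <- 0
  pmax(u * scale, 0)
}
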