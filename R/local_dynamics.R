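#' Local (non-spatial) reaction rates of the two-sex model
#'
#' Evaluates the reaction part of the model at given female and male
#' densities: births arise from mass-action encounters of the sexes,
#' succeed in proportion to the unoccupied fraction `1 - f - m` of the
#' environment, and are split between the sexes by the birth sex ratio `r`;
#' each sex additionally suffers density-independent mortality.
#'
#' @param f,m Female and male densities (occupancy fractions), non-negative.
#'   Vectorized; recycled to a common length.
#' @param params A [model_params()] object.
#' @return A list with components `df_dt` and `dm_dt`.
#' @examples
#' p <- model_params(0.5, 0.05, 0.05)
#' local_rates(0.3, 0.3, p)
#' @export
local_rates <- function(f, m, params) {
  stopifnot(inherits(params, "model_params"))
  if (any(f < 0) || any(m < 0)) stop("densities must be non-negative")
  s <- 1 - f - m
  births <- params$sigma * f * m * s
  list(df_dt = params$r * births - params$mu_f * f,
       dm_dt = (1 - params$r) * births - params$mu_m * m)
}

#' Local reaction rate of the single-sex reduction
#'
#' The cubic growth law \eqn{g(u) = (\sigma/2) u^2 (1 - 2u) - \mu u},
#' i.e. [local_rates()] evaluated on the symmetric diagonal
#' \eqn{f = m = u} with \eqn{r = 1/2} and equal mortalities. It factorizes
#' as \eqn{g(u) = -\sigma u (u - u_-)(u - u_+)}, a Nagumo-type cubic with a
#' strong Allee effect: growth is negative below the Allee threshold
#' \eqn{u_-} and positive between \eqn{u_-} and the carrying density
#' \eqn{u_+}.
#'
#' @param u Density (occupancy fraction), non-negative; vectorized.
#' @param p A [single_sex_params()] object.
#' @return Numeric vector of rates \eqn{du/dt}.
#' @export
single_sex_rate <- function(u, p) {
  stopifnot(inherits(p, "single_sex_params"))
  if (any(u < 0)) stop("densities must be non-negative")
  p$sigma / 2 * u^2 * (1 - 2 * u) - p$mu * u
}

# derivative g'(u), used for phase-plane classification and period limits
single_sex_rate_deriv <- function(u, p) {
  p$sigma * u - 3 * p$sigma * u^2 - p$mu
}

#' Existence of a positive stable equilibrium
#'
#' The two-sex local dynamics has a pair of positive equilibria (an
#' unstable Allee point and a stable persistence point) if and only if
#' \deqn{A \equiv \mu_f / r + \mu_m / (1 - r) < \sigma / 4,}
#' strictly. Under the symmetric reduction this becomes
#' \eqn{\mu < \sigma / 16}.
#'
#' @param params A [model_params()] object.
#' @return Logical.
#' @export
stability_condition_two_sex <- function(params) {
  stopifnot(inherits(params, "model_params"))
  A <- params$mu_f / params$r + params$mu_m / (1 - params$r)
  A < params$sigma / 4
}

#' @rdname stability_condition_two_sex
#' @param p A [single_sex_params()] object.
#' @export
stability_condition_single_sex <- function(p) {
  stopifnot(inherits(p, "single_sex_params"))
  p$mu < p$sigma / 16
}

#' Admissible band of birth sex ratios
#'
#' For fixed mortalities, the open interval of `r` values on which the
#' positive equilibria exist (`A(r) < sigma/4`). The interval is empty when
#' even the optimal sex ratio fails the condition.
#'
#' @param mu_f,mu_m Mortality rates.
#' @param sigma Birth-rate scale, default 1.
#' @return Numeric length-2 vector `c(lower, upper)` (open interval), or
#'   `c(NA, NA)` if empty.
#' @export
admissible_r_range <- function(mu_f, mu_m, sigma = 1) {
  # A(r) < sigma/4  <=>  (sigma/4) r^2 - (sigma/4 - mu_m + mu_f) r + mu_f < 0
  a <- sigma / 4
  b <- -(sigma / 4 - mu_m + mu_f)
  cc <- mu_f
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) return(c(NA_real_, NA_real_))
  root <- sqrt(disc)
  lo <- (-b - root) / (2 * a)
  hi <- (-b + root) / (2 * a)
  c(max(lo, 0), min(hi, 1))
}

# numerical Jacobian of the local rates (central differences)
local_jacobian <- function(f, m, params, h = 1e-7) {
  rate_vec <- function(x) {
    # allow small negative excursions from differencing near zero
    s <- 1 - x[1] - x[2]
    births <- params$sigma * x[1] * x[2] * s
    c(params$r * births - params$mu_f * x[1],
      (1 - params$r) * births - params$mu_m * x[2])
  }
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- h
    J[, j] <- (rate_vec(c(f, m) + e) - rate_vec(c(f, m) - e)) / (2 * h)
  }
  J
}

#' Fixed points of the local two-sex dynamics
#'
#' Solves for the spatially homogeneous equilibria. Writing `s = 1 - f - m`
#' for the vacant fraction, the positive equilibria satisfy
#' \eqn{s (1 - s) = A / \sigma} with \eqn{A = \mu_f/r + \mu_m/(1-r)}; each
#' root maps to densities
#' \eqn{f^* = \mu_m / ((1-r) \sigma s)}, \eqn{m^* = \mu_f / (r \sigma s)}.
#' The smaller root of `s` gives the stable persistence point, the larger
#' the unstable Allee point; extinction `(0, 0)` always exists. Stability
#' labels are assigned from the eigenvalues of a numerically differenced
#' Jacobian rather than hand-derived formulas.
#'
#' @param params A [model_params()] object.
#' @return An object of class `equilibrium_set`: list with `exists`,
#'   `extinction`, `allee`, `persistence` (each a named `c(f =, m =)`
#'   vector, the latter two `NULL` when `exists` is `FALSE`),
#'   `allee_total`, `persistence_total`, `s_values` (vacant-fraction roots,
#'   ascending = persistence then Allee), and `eigenvalues` per point.
#' @examples
#' equilibria(model_params(0.5, 0.05, 0.05))
#' @export
equilibria <- function(params) {
  stopifnot(inherits(params, "model_params"))
  A <- params$mu_f / params$r + params$mu_m / (1 - params$r)
  sig <- params$sigma
  out <- list(exists = FALSE,
              extinction = c(f = 0, m = 0),
              allee = NULL, persistence = NULL,
              allee_total = NA_real_, persistence_total = NA_real_,
              s_values = c(NA_real_, NA_real_),
              eigenvalues = list(
                extinction = eigen(local_jacobian(0, 0, params),
                                   only.values = TRUE)$values))
  if (A < sig / 4) {
    root <- sqrt(1 / 4 - A / sig)
    s_pers <- 1 / 2 - root   # higher total density: persistence
    s_allee <- 1 / 2 + root
    to_point <- function(s) c(f = params$mu_m / ((1 - params$r) * sig * s),
                              m = params$mu_f / (params$r * sig * s))
    pers <- to_point(s_pers)
    alle <- to_point(s_allee)
    out$exists <- TRUE
    out$persistence <- pers
    out$allee <- alle
    out$persistence_total <- sum(pers)
    out$allee_total <- sum(alle)
    out$s_values <- c(persistence = s_pers, allee = s_allee)
    out$eigenvalues$persistence <-
      eigen(local_jacobian(pers[1], pers[2], params), only.values = TRUE)$values
    out$eigenvalues$allee <-
      eigen(local_jacobian(alle[1], alle[2], params), only.values = TRUE)$values
  }
  class(out) <- "equilibrium_set"
  out
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat("Local equilibria of the two-sex dynamics\n")
  cat("  extinction: (0, 0)  [stable]\n")
  if (!x$exists) {
    cat("  no positive equilibria (stability condition fails)\n")
    return(invisible(x))
  }
  cat(sprintf("  Allee (unstable):      f = %.6g, m = %.6g  (total %.6g)\n",
              x$allee[1], x$allee[2], x$allee_total))
  cat(sprintf("  persistence (stable):  f = %.6g, m = %.6g  (total %.6g)\n",
              x$persistence[1], x$persistence[2], x$persistence_total))
  invisible(x)
}

#' Closed-form equilibrium densities of the single-sex reduction
#'
#' Roots \eqn{u_\pm = 1/4 \pm \sqrt{1/16 - \mu/\sigma}} of the cubic growth
#' law: `u_minus` is the Allee threshold, `u_plus` the carrying density.
#'
#' @param p A [single_sex_params()] object.
#' @return List with `exists`, `u_minus`, `u_plus`.
#' @export
single_sex_roots <- function(p) {
  stopifnot(inherits(p, "single_sex_params"))
  disc <- 1 / 16 - p$mu / p$sigma
  if (disc <= 0) return(list(exists = FALSE, u_minus = NA_real_, u_plus = NA_real_))
  list(exists = TRUE, u_minus = 1 / 4 - sqrt(disc), u_plus = 1 / 4 + sqrt(disc))
}

#' Density-maximizing sex ratio at birth
#'
#' The equilibrium total density `1 - s` depends on the sex ratio only
#' through \eqn{A(r) = \mu_f/r + \mu_m/(1-r)} and is maximized where `A` is
#' minimized, giving the closed form
#' \deqn{r^* = \sqrt{\mu_f} / (\sqrt{\mu_f} + \sqrt{\mu_m}).}
#' Equal mortalities give \eqn{r^* = 1/2}.
#'
#' @param mu_f,mu_m Mortality rates, > 0.
#' @return The optimal sex ratio, in (0, 1).
#' @examples
#' optimal_sex_ratio(0.04, 0.01)  # 2/3: bias toward the higher-mortality sex
#' @export
optimal_sex_ratio <- function(mu_f, mu_m) {
  stopifnot(mu_f > 0, mu_m > 0)
  sqrt(mu_f) / (sqrt(mu_f) + sqrt(mu_m))
}
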