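#' Two-sex model parameters
#'
#' Bundle of rate constants and diffusion coefficients for the two-sex
#' reaction-diffusion model
#' \deqn{\partial_t f = D_f f_{xx} + \sigma r f m (1 - f - m) - \mu_f f}
#' \deqn{\partial_t m = D_m m_{xx} + \sigma (1-r) f m (1 - f - m) - \mu_m m}
#' where \eqn{f} and \eqn{m} are local female and male densities measured as
#' occupancy fractions, \eqn{r} is the fraction of offspring born female,
#' \eqn{\mu_f, \mu_m} are density-independent mortality rates, and the birth
#' term is mass-action mating damped by the unoccupied fraction
#' \eqn{1 - f - m} of the environment.
#'
#' @param r Sex ratio at birth: fraction of offspring born female, in (0,1).
#' @param mu_f,mu_m Female and male per-capitum mortality rates (1/time), > 0.
#' @param D_f,D_m Female and male diffusion coefficients (length^2/time), >= 0.
#' @param sigma Mating/birth rate scale (1/(density*time)), > 0. Default 1;
#'   all thresholds scale with it.
#' @return An object of class `model_params`.
#' @examples
#' model_params(r = 0.5, mu_f = 0.05, mu_m = 0.05)
#' @export
model_params <- function(r, mu_f, mu_m, D_f = 1, D_m = 1, sigma = 1) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r),
            is.numeric(mu_f), length(mu_f) == 1L,
            is.numeric(mu_m), length(mu_m) == 1L,
            is.numeric(D_f), length(D_f) == 1L,
            is.numeric(D_m), length(D_m) == 1L,
            is.numeric(sigma), length(sigma) == 1L)
  if (r <= 0 || r >= 1) stop("`r` must lie strictly inside (0, 1)")
  if (mu_f <= 0 || mu_m <= 0) stop("mortality rates must be positive")
  if (D_f < 0 || D_m < 0) stop("diffusion coefficients must be non-negative")
  if (sigma <= 0) stop("`sigma` must be positive")
  structure(list(r = r, mu_f = mu_f, mu_m = mu_m,
                 D_f = D_f, D_m = D_m, sigma = sigma),
            class = "model_params")
}

#' Single-sex (symmetric reduction) parameters
#'
#' Parameters of the reduced scalar equation
#' \deqn{\partial_t u = D u_{xx} + (\sigma/2) u^2 (1 - 2u) - \mu u,}
#' obtained from the two-sex model by setting \eqn{r = 1/2},
#' \eqn{\mu_f = \mu_m = \mu}, \eqn{D_f = D_m = D} and identical initial
#' distributions, so that \eqn{f = m = u} for all time.
#'
#' @param mu Mortality rate (1/time), > 0.
#' @param D Diffusion coefficient (length^2/time), >= 0.
#' @param sigma Birth-rate scale, > 0; default 1.
#' @return An object of class `single_sex_params`.
#' @export
single_sex_params <- function(mu, D = 1, sigma = 1) {
  stopifnot(is.numeric(mu), length(mu) == 1L,
            is.numeric(D), length(D) == 1L,
            is.numeric(sigma), length(sigma) == 1L)
  if (mu <= 0) stop("`mu` must be positive")
  if (D < 0) stop("`D` must be non-negative")
  if (sigma <= 0) stop("`sigma` must be positive")
  structure(list(mu = mu, D = D, sigma = sigma), class = "single_sex_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Two-sex model parameters\n")
  cat(sprintf("  r (fraction born female): %.6g\n", x$r))
  cat(sprintf("  mortality  mu_f = %.6g, mu_m = %.6g\n", x$mu_f, x$mu_m))
  cat(sprintf("  diffusion  D_f  = %.6g, D_m  = %.6g\n", x$D_f, x$D_m))
  cat(sprintf("  birth-rate scale sigma = %.6g\n", x$sigma))
  invisible(x)
}

#' @export
print.single_sex_params <- function(x, ...) {
  cat(sprintf("Single-sex parameters: mu = %.6g, D = %.6g, sigma = %.6g\n",
              x$mu, x$D, x$sigma))
  invisible(x)
}

#' Convert between the symmetric two-sex model and its single-sex reduction
#'
#' `as_single_sex()` requires symmetric two-sex parameters
#' (`r = 1/2`, equal mortalities and diffusivities); `as_two_sex()` embeds
#' single-sex parameters as the equivalent symmetric two-sex set.
#'
#' @param params A `model_params` object with symmetric parameters.
#' @return `as_single_sex()`: a `single_sex_params`; `as_two_sex()`: a
#'   `model_params`.
#' @export
as_single_sex <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$r != 0.5 || params$mu_f != params$mu_m || params$D_f != params$D_m)
    stop("parameters are not symmetric (need r = 1/2, mu_f = mu_m, D_f = D_m)")
  single_sex_params(mu = params$mu_f, D = params$D_f, sigma = params$sigma)
}

#' @rdname as_single_sex
#' @param p A `single_sex_params` object.
#' @export
as_two_sex <- function(p) {
  stopifnot(inherits(p, "single_sex_params"))
  model_params(r = 0.5, mu_f = p$mu, mu_m = p$mu, D_f = p$D, D_m = p$D,
               sigma = p$sigma)
}
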