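#' Write and read a density state as CSV
#'
#' Columns `x, f, m`; full double precision, round-trips exactly through
#' the reader.
#'
#' @param state A [state_field()].
#' @param grid The [grid_1d()] the state lives on.
#' @param path Output file path.
#' @return `path`, invisibly (writer); a list `list(state, x)` (reader).
#' @export
write_state_csv <- function(state, grid, path) {
  check_state_grid(state, grid)
  df <- data.frame(x = grid$x, f = state$f, m = state$m)
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_state_csv
#' @export
read_state_csv <- function(path) {
  df <- utils::read.csv(path)
  list(state = state_field(df$f, df$m), x = df$x)
}

#' Write and read a cost report as JSON
#'
#' A cost report records a method label (one of `aperiodic_nucleus`,
#' `rectangular_equal`, `rectangular_unequal`, `annealed`), the model
#' parameters, the achieved cost and free-form diagnostics.
#'
#' @param method Method label.
#' @param params A [model_params()].
#' @param cost Achieved restoration cost.
#' @param diagnostics Named list of scalar diagnostics (optional).
#' @param path Output file path.
#' @return `path`, invisibly (writer); the report list (reader).
#' @export
write_cost_report <- function(method, params, cost, diagnostics = list(),
                              path) {
  method <- match.arg(method, c("aperiodic_nucleus", "rectangular_equal",
                                "rectangular_unequal", "annealed"))
  stopifnot(cost >= 0)
  rep <- list(method = method, params = unclass(params), cost = cost,
              diagnostics = diagnostics)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cost_report
#' @export
read_cost_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep$params <- do.call(model_params, as.list(rep$params))
  rep
}

#' Load a run configuration from JSON
#'
#' Reads a JSON file with optional blocks `params` (arguments of
#' [model_params()]), `grid` (arguments of [grid_1d()]) and `integration`
#' (arguments of [integration_config()]).
#'
#' @param path JSON file path.
#' @return List with `params`, `grid`, `integration` (those present).
#' @export
load_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list()
  if (!is.null(cfg$params)) out$params <- do.call(model_params, as.list(cfg$params))
  if (!is.null(cfg$grid)) out$grid <- do.call(grid_1d, as.list(cfg$grid))
  if (!is.null(cfg$integration))
    out$integration <- do.call(integration_config, as.list(cfg$integration))
  out
}

#' Generate parameter-sweep and release-shape fixtures
#'
#' Writes small plain-text fixtures for tests and examples: a CSV sweep of
#' admissible parameter sets (every row satisfies the positive-equilibrium
#' condition, including the canonical symmetric set `mu = 0.05`, `D = 1`,
#' `r = 0.5`) and a CSV of canned rectangular release shapes.
#'
#' @param dir Output directory (created if needed).
#' @param mu_values,r_values,D_values Sweep grids; defaults give a small
#'   admissible sweep.
#' @return Character vector of the files written.
#' @export
generate_fixtures <- function(dir,
                              mu_values = c(0.02, 0.03, 0.05),
                              r_values = c(0.4, 0.5, 0.6),
                              D_values = c(0.5, 1, 2)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sweep <- expand.grid(r = r_values, mu_f = mu_values, mu_m = mu_values,
                       D_f = D_values, D_m = D_values, sigma = 1)
  keep <- vapply(seq_len(nrow(sweep)), function(i)
    stability_condition_two_sex(do.call(model_params, as.list(sweep[i, ]))),
    logical(1))
  sweep <- sweep[keep, , drop = FALSE]
  if (!any(sweep$r == 0.5 & sweep$mu_f == 0.05 & sweep$mu_m == 0.05 &
           sweep$D_f == 1 & sweep$D_m == 1))
    sweep <- rbind(sweep, data.frame(r = 0.5, mu_f = 0.05, mu_m = 0.05,
                                     D_f = 1, D_m = 1, sigma = 1))
  f_params <- file.path(dir, "param_sweep.csv")
  utils::write.csv(sweep, f_params, row.names = FALSE, quote = FALSE)

  shapes <- data.frame(label = c("narrow", "canonical", "wide"),
                       n_f = c(0.3, 0.36, 0.36), n_m = c(0.3, 0.36, 0.36),
                       L_f = c(5, 15, 40), L_m = c(5, 15, 40))
  f_shapes <- file.path(dir, "release_shapes.csv")
  utils::write.csv(shapes, f_shapes, row.names = FALSE, quote = FALSE)
  c(f_params, f_shapes)
}
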