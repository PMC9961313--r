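#' Truncated-series exact solution of the worked example
#'
#' For the time-dependent killing-rate example with initial condition
#' `e^(k x)` the reference solution is the truncated power series
#'
#' `C(x, t) = e^(k x) (1 + k^2 t^alpha / Gamma(1 + alpha)
#'                       + k^4 t^(2 alpha) / Gamma(1 + 2 alpha))`.
#'
#' This is the printed two-term correction, not the full solution of the
#' model: killing-rate correction terms of order `t^(alpha + 2)` and
#' higher are omitted, so for small `t` it serves as the validation
#' reference.  At `t = 0` it reduces to the initial condition.
#'
#' @param x,t Evaluation point(s); vectorized.
#' @param spec A [series_solution_spec()], or `NULL` to use `alpha` and
#'   `k_exp` directly.
#' @param alpha Fractional order in `(0, 1]`.
#' @param k_exp Exponent `k` of the initial profile `e^(k x)`; the
#'   worked example uses `k = -1` (a decaying cell-concentration
#'   profile).
#' @return Numeric value(s) of the crisp series factor.
#' @examples
#' exact_crisp(4, 0.05, alpha = 0.9)   # ~0.019650
#' @export
exact_crisp <- function(x, t, spec = NULL, alpha = spec$alpha,
                        k_exp = spec$k_exp) {
  if (!is.null(spec)) stopifnot(inherits(spec, "series_solution_spec"))
  stopifnot(is.numeric(alpha), is.numeric(k_exp))
  if (alpha <= 0 || alpha > 1) abort("alpha must lie in (0, 1].")
  if (any(t < 0)) abort("t must be nonnegative.")
  exp(k_exp * x) * (1 +
    k_exp^2 * t^alpha / gamma(1 + alpha) +
    k_exp^4 * t^(2 * alpha) / gamma(1 + 2 * alpha))
}

#' Series-solution parameters for the worked example
#'
#' @param k_exp Exponent of the `e^(k x)` profile.
#' @param alpha Fractional order in `(0, 1]`.
#' @return An object of class `series_solution_spec`.
#' @export
series_solution_spec <- function(k_exp = -1, alpha = 0.9) {
  stopifnot(is.numeric(k_exp), length(k_exp) == 1,
            is.numeric(alpha), length(alpha) == 1)
  if (alpha <= 0 || alpha > 1) abort("alpha must lie in (0, 1].")
  structure(list(k_exp = k_exp, alpha = alpha),
            class = "series_solution_spec")
}

#' Fuzzy branch of the series solution
#'
#' The fuzzy initial condition of the worked example is
#' `phi(r, beta) e^(k x)` with `phi` the double parametric value of a
#' triangular scale; by linearity of the model the fuzzy exact solution
#' is `phi(r, beta) * C(x, t)` with `C` from [exact_crisp()] -- the
#' scale multiplies the entire series, which is what forces the solution
#' (and its error) to vanish identically at `r = 1`.
#'
#' @inheritParams exact_crisp
#' @param phi_source The triangular scale of the initial condition
#'   (worked example: `tri_fuzzy(-1, 0, 1)`).
#' @param r,beta Double parametric sample in `[0, 1]`.
#' @return Numeric value(s) `phi(r, beta) * C(x, t)`.
#' @export
exact_fuzzy <- function(x, t, spec = NULL, phi_source, r, beta,
                        alpha = spec$alpha, k_exp = spec$k_exp) {
  phi <- double_param_value(phi_source, r, beta)
  phi * exact_crisp(x, t, alpha = alpha, k_exp = k_exp)
}

#' Closed-form heat-equation reference
#'
#' The classical limit check: for `alpha = 1`, zero killing rate,
#' initial condition `sin(pi x)` and zero Dirichlet data on `[0, 1]`,
#' the solution is `e^(-pi^2 t) sin(pi x)`.
#'
#' @param x,t Evaluation point(s); vectorized.
#' @return Numeric value(s).
#' @export
classical_heat_exact <- function(x, t) {
  exp(-pi^2 * t) * sin(pi * x)
}

#' Naive direct-history reference stepper
#'
#' Re-derives the solution with a deliberately naive scalar
#' implementation: scalar loops over nodes and a full re-evaluation of
#' the Caputo memory sum at every node and level, with no vectorization
#' or caching.  It exists to cross-check the optimized stepper and is
#' restricted to small grids.
#'
#' @param model A crisp [model_spec()].
#' @param grid A [grid_spec()]; at most `max_nodes` nodes and levels.
#' @param max_nodes Refusal threshold for either grid dimension.
#' @return A `crisp_solution` computed by the naive path.
#' @export
direct_history_oracle <- function(model, grid, max_nodes = 200L) {
  stopifnot(inherits(model, "model_spec"), inherits(grid, "grid_spec"))
  if (grid$M + 1L > max_nodes || grid$N + 1L > max_nodes) {
    abort(sprintf(
      "direct_history_oracle is restricted to grids of at most %d nodes/levels; use solve_crisp() for production runs.",
      max_nodes))
  }
  coeff <- scheme_coefficients(grid)
  b <- caputo_weights(grid$alpha, max(1L, grid$N))$b
  M <- grid$M
  N <- grid$N
  x <- x_nodes(grid)
  U <- matrix(NA_real_, N + 1L, M + 1L)
  U[1L, ] <- model$ic(x)
  U[1L, 1L] <- model$bc_left(0)
  U[1L, M + 1L] <- model$bc_right(0)
  for (n in 0:(N - 1L)) {
    U[n + 2L, 1L] <- model$bc_left((n + 1L) * grid$dt)
    U[n + 2L, M + 1L] <- model$bc_right((n + 1L) * grid$dt)
    for (i in 2:M) {
      k_val <- model$k_fn(x[i], n * grid$dt)
      memory <- 0
      if (n >= 1L) {
        for (j in 1:n) {
          memory <- memory + b[j] * (U[n + 2L - j, i] - U[n + 1L - j, i])
        }
      }
      U[n + 2L, i] <- coeff$s * (U[n + 1L, i + 1L] + U[n + 1L, i - 1L]) +
        (1 - 2 * coeff$s) * U[n + 1L, i] -
        coeff$rho * k_val * U[n + 1L, i] - memory
    }
    if (any(!is.finite(U[n + 2L, ]))) {
      abort(sprintf("Non-finite values at time level %d.", n + 1L))
    }
  }
  structure(
    list(u = U, grid = grid, coeff = coeff,
         weights = caputo_weights(grid$alpha, max(1L, grid$N)),
         stability = stability_report(
           grid, max(abs(outer_k(model$k_fn, x, t_levels(grid))))),
         stepper = "direct-history", boundary_mode = model$boundary_mode),
    class = "crisp_solution"
  )
}

#' Numerical-vs-exact error table for a fuzzy solution
#'
#' Compares a computed [solve_fuzzy()] bundle with the fuzzy series
#' reference at the requested grid nodes, one row per
#' `(r, beta, x, t)` combination -- the layout of the worked example's
#' published error table.
#'
#' @param bundle A `fuzzy_solution` from [solve_fuzzy()].
#' @param spec A [series_solution_spec()] for the exact reference.
#' @param phi_source Triangular scale of the fuzzy initial condition.
#' @param x_eval,t_eval Evaluation coordinates; every value must
#'   coincide with a grid node.
#' @return A tibble with columns `r`, `beta`, `x`, `t`, `numerical`,
#'   `exact`, `abs_error`.
#' @export
abs_error_table <- function(bundle, spec, phi_source,
                            x_eval = 4, t_eval = 0.05) {
  stopifnot(inherits(bundle, "fuzzy_solution"),
            inherits(spec, "series_solution_spec"),
            is_tri_fuzzy(phi_source))
  pts <- tidyr::expand_grid(x = x_eval, t = t_eval)
  purrr::pmap(pts, function(x, t) {
    num <- solution_at(bundle, x, t)
    num$exact <- exact_fuzzy(x, t, spec, phi_source, num$r, num$beta)
    num
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(
      numerical = .data$u,
      abs_error = abs(.data$numerical - .data$exact)
    ) |>
    dplyr::select("r", "beta", "x", "t", "numerical", "exact", "abs_error")
}
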