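#' Sufficient stability bound (proposition form)
#'
#' The Fourier analysis of the regrouped scheme gives the sufficient
#' condition `s <= (1 - rho k_max - b_1) / 4`, where
#' `rho = dt^alpha Gamma(2 - alpha)`, `b_1 = 2^(1 - alpha) - 1` is the
#' first Caputo weight, and `k_max` bounds the killing rate over the
#' run.  This is the operative stability check in the package: it is the
#' more conservative of the two printed bounds and the one derived
#' term-by-term.  At `alpha = 1`, `k_max = 0` it reduces to the
#' classical explicit limit `s <= 1/4` used in the derivation.
#'
#' @param coeff A [scheme_coefficients()].
#' @param weights A [caputo_weights()] for the run (only `b_1` enters).
#' @param k_max Maximum of `|k(x, t)|` over the grid.
#' @return The bound on `s` (may be non-positive, meaning no stable `s`).
#' @export
stability_bound_prop1 <- function(coeff, weights, k_max) {
  stopifnot(inherits(coeff, "scheme_coefficients"),
            inherits(weights, "caputo_weights"),
            is.numeric(k_max), k_max >= 0)
  b1 <- if (coeff$alpha == 1) 0 else weights$b[1L]
  (1 - coeff$rho * k_max - b1) / 4
}

#' Sufficient stability bound (theorem form, literal reading)
#'
#' The companion stability statement prints as
#' `s <= 1 / (4 - s dx^2 k)`.  Read literally (with `s` on the right
#' evaluated at the run's own value) it conflicts with the
#' proposition-form bound whenever `b_1 > 0`; it is computed here under
#' that literal reading and reported side-by-side for comparison only --
#' [stability_bound_prop1()] is the operative check.
#'
#' @inheritParams stability_bound_prop1
#' @param grid The [grid_spec()] supplying `dx`.
#' @return The literal bound, or `Inf` (with a warning) when the
#'   denominator is not positive.
#' @export
stability_bound_thm1 <- function(coeff, grid, k_max) {
  stopifnot(inherits(coeff, "scheme_coefficients"),
            inherits(grid, "grid_spec"),
            is.numeric(k_max), k_max >= 0)
  denom <- 4 - coeff$s * grid$dx^2 * k_max
  if (denom <= 0) {
    warn("Theorem-form denominator is not positive; bound reported as unbounded.")
    return(Inf)
  }
  1 / denom
}

#' Stability report for a run configuration
#'
#' Computes both printed stability bounds and the verdicts for the run's
#' fractional diffusion number `s`.
#'
#' @param grid A [grid_spec()].
#' @param k_max Maximum `|k(x, t)|` over the run's nodes and levels (for
#'   fuzzy killing rates, evaluated at the worst-case upper branch).
#' @return An object of class `stability_report` with fields `s`, `b1`,
#'   `k_max`, `bound_prop1`, `bound_thm1`, `stable_prop1`,
#'   `stable_thm1`.
#' @examples
#' stability_report(grid_spec(8, 0.05, 0.5, 0.01, 0.9), k_max = 0.0025)
#' @export
stability_report <- function(grid, k_max = 0) {
  stopifnot(inherits(grid, "grid_spec"))
  coeff <- scheme_coefficients(grid)
  weights <- caputo_weights(grid$alpha, 1L)
  bound1 <- stability_bound_prop1(coeff, weights, k_max)
  bound2 <- stability_bound_thm1(coeff, grid, k_max)
  structure(
    list(s = coeff$s,
         b1 = if (grid$alpha == 1) 0 else weights$b[1L],
         k_max = k_max,
         bound_prop1 = bound1, bound_thm1 = bound2,
         stable_prop1 = coeff$s <= bound1,
         stable_thm1 = coeff$s <= bound2),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    paste0("<stability_report s = %.4g, b1 = %.4g, k_max = %.4g\n",
           "  proposition bound %.4g -> %s; theorem bound %.4g -> %s>\n"),
    x$s, x$b1, x$k_max,
    x$bound_prop1, if (x$stable_prop1) "stable" else "UNSTABLE",
    x$bound_thm1, if (x$stable_thm1) "stable" else "UNSTABLE"))
  invisible(x)
}

#' @export
tidy.stability_report <- function(x, ...) {
  tibble(
    s = x$s, b1 = x$b1, k_max = x$k_max,
    bound_prop1 = x$bound_prop1, bound_thm1 = x$bound_thm1,
    stable_prop1 = x$stable_prop1, stable_thm1 = x$stable_thm1
  )
}

#' Discrete L2 error norm
#'
#' The weighted norm used by the stability analysis:
#' `||eps||_2 = sqrt( sum_i h * eps_i^2 )` over the interior nodes, with
#' `h` the space step.
#'
#' @param eps Numeric vector of interior error values.
#' @param h Space step (positive).
#' @return The norm (scalar).
#' @examples
#' l2_error_norm(c(3, 4), h = 1)  # 5
#' @export
l2_error_norm <- function(eps, h) {
  if (length(eps) == 0) abort("eps must be non-empty.")
  stopifnot(is.numeric(eps), is.numeric(h))
  if (h <= 0) abort("h must be positive.")
  sqrt(sum(h * eps^2))
}

#' Empirical perturbation probe
#'
#' Verifies the stability prediction on a concrete run: the model is
#' solved twice, once from the initial condition `f` and once from
#' `f + delta` with `delta` a seeded uniform perturbation of the
#' interior nodes (boundaries stay pinned to the boundary data).  Because
#' the scheme is linear, the difference of the two runs evolves exactly
#' as the round-off error recursion, so under the stability bound the
#' norm ratios `||eps^n||_2 / ||eps^0||_2` must never exceed 1.
#'
#' @param model A crisp [model_spec()].
#' @param grid A [grid_spec()].
#' @param seed Integer seed for the perturbation draw.
#' @param magnitude Scale of the uniform perturbation
#'   (`delta ~ magnitude * U(-1, 1)`); must be positive.
#'
#' @return An object of class `perturbation_probe`: a tibble
#'   `ratios` with columns `n`, `t`, `norm_ratio`, plus `max_ratio`,
#'   `seed`, `magnitude` and the run's [stability_report()].
#' @examples
#' \donttest{
#' cfg <- preset_worked_example()
#' probe <- perturbation_probe(at_sample(cfg$model, 0, 0), cfg$grid, seed = 1)
#' probe$max_ratio
#' }
#' @export
perturbation_probe <- function(model, grid, seed = 1L, magnitude = 1e-6) {
  stopifnot(inherits(model, "model_spec"), inherits(grid, "grid_spec"))
  if (!is.numeric(magnitude) || magnitude <= 0) {
    abort("magnitude must be positive.")
  }
  M <- grid$M
  delta <- withr::with_seed(as.integer(seed), {
    magnitude * runif(M - 1L, -1, 1)
  })
  base <- solve_crisp(model, grid, warn_unstable = FALSE)
  ic_pert <- function(x) {
    v <- model$ic(x)
    i <- round(x / grid$dx)
    inner <- i >= 1 & i <= M - 1L
    v[inner] <- v[inner] + delta[i[inner]]
    v
  }
  pert_model <- model_spec(ic = ic_pert, k_fn = model$k_fn,
                           bc_left = model$bc_left, bc_right = model$bc_right,
                           boundary_mode = model$boundary_mode)
  pert <- solve_crisp(pert_model, grid, warn_unstable = FALSE)
  norm0 <- l2_error_norm(delta, grid$dx)
  ratios <- purrr::map_dbl(1:grid$N, function(n) {
    eps <- pert$u[n + 1L, 2:M] - base$u[n + 1L, 2:M]
    l2_error_norm(eps, grid$dx) / norm0
  })
  structure(
    list(ratios = tibble(n = 1:grid$N, t = (1:grid$N) * grid$dt,
                         norm_ratio = ratios),
         max_ratio = max(ratios),
         seed = as.integer(seed), magnitude = magnitude,
         stability = base$stability, grid = grid),
    class = "perturbation_probe"
  )
}

#' @export
print.perturbation_probe <- function(x, ...) {
  cat(sprintf(
    "<perturbation_probe seed %d, magnitude %.2g: max ||eps^n||/||eps^0|| = %.6g (%s)>\n",
    x$seed, x$magnitude, x$max_ratio,
    if (x$max_ratio <= 1 + 1e-9) "no growth" else "GROWTH"))
  invisible(x)
}

#' @export
tidy.perturbation_probe <- function(x, ...) x$ratios

#' @export
glance.perturbation_probe <- function(x, ...) {
  tibble(
    max_ratio = x$max_ratio, seed = x$seed, magnitude = x$magnitude,
    s = x$stability$s, bound_prop1 = x$stability$bound_prop1,
    stable_prop1 = x$stability$stable_prop1
  )
}
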