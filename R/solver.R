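#' One explicit time step (memory-sum form)
#'
#' Advances the interior nodes one time level with the explicit scheme:
#' centered second difference in space, Caputo memory in time,
#'
#' `u_i^{n+1} = s (u_{i+1}^n + u_{i-1}^n) + (1 - 2 s) u_i^n
#'   - rho k(x_i, t_n) u_i^n
#'   - sum_{j=1}^{n} b_j (u_i^{n+1-j} - u_i^{n-j})`,
#'
#' where `s` and `rho` come from [scheme_coefficients()] and `b_j` from
#' [caputo_weights()].  At `n = 0` the memory sum is empty; at
#' `alpha = 1` all `b_j` vanish and the step is the classical explicit
#' (FTCS) update.  The killing rate is evaluated at the known level
#' `t_n`, consistent with the other explicit terms.
#'
#' @param history Numeric matrix of computed levels: row `m` holds time
#'   level `m - 1`, columns are the `M + 1` space nodes.  Rows
#'   `1..(n+1)` must be populated.
#' @param n The level being advanced from (`0`-based); the step returns
#'   level `n + 1`.
#' @param coeff A [scheme_coefficients()].
#' @param weights A [caputo_weights()] with at least `n` weights.
#' @param k_fn Crisp killing rate, a function of `(x, t)` vectorized in
#'   `x`.
#' @param grid The [grid_spec()] supplying node coordinates.
#'
#' @return Numeric vector of the `M - 1` interior values at level
#'   `n + 1` (boundaries are imposed by the caller).
#' @seealso [explicit_step_regrouped()] for the algebraically identical
#'   regrouped form used by the stability analysis.
#' @export
explicit_step <- function(history, n, coeff, weights, k_fn, grid) {
  check_step_args(history, n, coeff, weights, grid)
  M <- grid$M
  int <- 2:M
  un <- history[n + 1L, ]
  x_int <- (int - 1L) * grid$dx
  t_n <- n * grid$dt
  new <- coeff$s * (un[int + 1L] + un[int - 1L]) +
    (1 - 2 * coeff$s) * un[int] -
    coeff$rho * k_fn(x_int, t_n) * un[int]
  if (n >= 1L) {
    b <- weights$b
    for (j in seq_len(n)) {
      new <- new - b[j] * (history[n + 2L - j, int] - history[n + 1L - j, int])
    }
  }
  new
}

#' One explicit time step (regrouped form)
#'
#' The same update as [explicit_step()] with the memory sum telescoped
#' onto the solution levels themselves:
#'
#' `u_i^{n+1} = s u_{i+1}^n + (1 - 2 s - rho k - b_1) u_i^n + s u_{i-1}^n
#'   - sum_{j=1}^{n-1} (b_{j+1} - b_j) u_i^{n-j} + b_n u_i^0`.
#'
#' The two forms are algebraically identical and must agree to floating
#' point roundoff; the regrouped form is the one the Fourier stability
#' analysis manipulates.
#'
#' @inheritParams explicit_step
#' @return Numeric vector of the `M - 1` interior values at level `n + 1`.
#' @export
explicit_step_regrouped <- function(history, n, coeff, weights, k_fn, grid) {
  check_step_args(history, n, coeff, weights, grid)
  M <- grid$M
  int <- 2:M
  un <- history[n + 1L, ]
  x_int <- (int - 1L) * grid$dx
  t_n <- n * grid$dt
  new <- coeff$s * (un[int + 1L] + un[int - 1L]) +
    (1 - 2 * coeff$s) * un[int] -
    coeff$rho * k_fn(x_int, t_n) * un[int]
  if (n >= 1L) {
    b <- weights$b
    new <- new - b[1L] * un[int]
    if (n >= 2L) {
      for (j in seq_len(n - 1L)) {
        new <- new - (b[j + 1L] - b[j]) * history[n + 1L - j, int]
      }
    }
    new <- new + b[n] * history[1L, int]
  }
  new
}

check_step_args <- function(history, n, coeff, weights, grid) {
  stopifnot(inherits(coeff, "scheme_coefficients"),
            inherits(weights, "caputo_weights"),
            inherits(grid, "grid_spec"),
            is.matrix(history))
  if (ncol(history) != grid$M + 1L) {
    abort("history must have M + 1 columns (one per space node).")
  }
  if (nrow(history) < n + 1L) {
    abort("history rows 0..n must be populated before stepping.")
  }
  if (n >= 1L && length(weights$b) < n) {
    abort("Caputo weights do not cover the requested level; recompute with a larger n_max.")
  }
  invisible(TRUE)
}

#' Solve a crisp model with the explicit Caputo scheme
#'
#' Runs the explicit finite-difference scheme over the full grid.  The
#' stability bounds are computed first and attached to the result; when
#' the fractional diffusion number `s` exceeds the operative
#' (Proposition-type) bound the solver warns and proceeds, so
#' instability experiments remain runnable.  Non-finite values abort
#' with the offending time level named.
#'
#' @param model A [model_spec()].
#' @param grid A [grid_spec()].
#' @param stepper `"memory"` (the literal memory-sum form, default) or
#'   `"regrouped"`; the two agree to roundoff.
#' @param warn_unstable Emit a warning when `s` exceeds the stability
#'   bound.
#'
#' @return An object of class `crisp_solution`: the `(N + 1) x (M + 1)`
#'   solution matrix `u`, the grid, the scheme coefficients, and a
#'   [stability_report()].  Use [tidy()] for a long tibble,
#'   [solution_at()] for point values.
#' @examples
#' g <- grid_spec(1, 0.05, 0.1, 0.001, alpha = 1)
#' m <- model_spec(ic = function(x) sin(pi * x))
#' sol <- solve_crisp(m, g)
#' solution_at(sol, x = 0.5, t = 0.05)
#' @export
solve_crisp <- function(model, grid,
                        stepper = c("memory", "regrouped"),
                        warn_unstable = TRUE) {
  stopifnot(inherits(model, "model_spec"), inherits(grid, "grid_spec"))
  stepper <- match.arg(stepper)
  step_fn <- if (stepper == "memory") explicit_step else explicit_step_regrouped

  coeff <- scheme_coefficients(grid)
  weights <- caputo_weights(grid$alpha, max(1L, grid$N))
  x <- x_nodes(grid)
  k_max <- max(abs(outer_k(model$k_fn, x, t_levels(grid))))
  report <- stability_report(grid, k_max)
  if (warn_unstable && !report$stable_prop1) {
    warn(sprintf(
      "s = %.4g exceeds the stability bound %.4g; the run may blow up.",
      report$s, report$bound_prop1))
  }

  M <- grid$M
  N <- grid$N
  U <- matrix(NA_real_, N + 1L, M + 1L)
  U[1L, ] <- model$ic(x)
  U[1L, 1L] <- model$bc_left(0)
  U[1L, M + 1L] <- model$bc_right(0)
  for (n in 0:(N - 1L)) {
    t_next <- (n + 1L) * grid$dt
    row <- numeric(M + 1L)
    row[1L] <- model$bc_left(t_next)
    row[M + 1L] <- model$bc_right(t_next)
    row[2:M] <- step_fn(U, n, coeff, weights, model$k_fn, grid)
    if (any(!is.finite(row))) {
      abort(sprintf(
        "Non-finite values at time level %d (t = %g); s = %.4g vs bound %.4g -- the scheme has blown up.",
        n + 1L, t_next, report$s, report$bound_prop1))
    }
    U[n + 2L, ] <- row
  }
  structure(
    list(u = U, grid = grid, coeff = coeff, weights = weights,
         stability = report, stepper = stepper,
         boundary_mode = model$boundary_mode),
    class = "crisp_solution"
  )
}

# evaluate k(x, t) on the full node/level lattice (rows: x, cols: t)
outer_k <- function(k_fn, x, t) {
  vapply(t, function(tn) k_fn(x, tn), numeric(length(x)))
}

#' @export
print.crisp_solution <- function(x, ...) {
  g <- x$grid
  cat(sprintf(
    "<crisp_solution %d x %d nodes (alpha = %g, s = %.4g, %s)>\n",
    g$N + 1L, g$M + 1L, g$alpha, x$coeff$s,
    if (x$stability$stable_prop1) "stable" else "UNSTABLE"))
  invisible(x)
}

#' Point value of a computed solution
#'
#' Looks up the solution at a space-time point that must coincide with a
#' grid node (no interpolation is performed).
#'
#' @param sol A `crisp_solution` or `fuzzy_solution`.
#' @param x,t Coordinates of a grid node.
#' @param ... Passed to methods; for fuzzy solutions, `r` and `beta`
#'   select the sample.
#' @return A numeric value (crisp) or a tibble over samples (fuzzy).
#' @export
solution_at <- function(sol, x, t, ...) UseMethod("solution_at")

#' @rdname solution_at
#' @export
solution_at.crisp_solution <- function(sol, x, t, ...) {
  g <- sol$grid
  i <- node_index(x, g$dx, g$M, "x")
  n <- node_index(t, g$dt, g$N, "t")
  sol$u[n, i]
}

#' @export
tidy.crisp_solution <- function(x, ...) {
  g <- x$grid
  out <- tidyr::expand_grid(n = 0:g$N, i = 0:g$M)
  out$t <- out$n * g$dt
  out$x <- out$i * g$dx
  out$u <- as.vector(t(x$u))
  dplyr::select(out, "n", "t", "i", "x", "u")
}

#' @export
glance.crisp_solution <- function(x, ...) {
  g <- x$grid
  tibble(
    alpha = g$alpha, dx = g$dx, dt = g$dt, L = g$L, t_end = g$t_end,
    s = x$coeff$s, rho = x$coeff$rho,
    bound_prop1 = x$stability$bound_prop1,
    stable_prop1 = x$stability$stable_prop1,
    max_abs_u = max(abs(x$u))
  )
}

#' Solve a fuzzy model over an (r, beta) sample grid
#'
#' Evaluates every fuzzy field of the model at each sample of the
#' double parametric grid and solves the resulting crisp problem, giving
#' the family of solutions whose `beta = 0` / `beta = 1` members are the
#' lower and upper fuzzy branches.
#'
#' @param fmodel A [fuzzy_model_spec()].
#' @param grid A [grid_spec()].
#' @param r_grid,beta_grid Sample grids in `[0, 1]`.  Defaults follow
#'   the worked example's tabulation: `r` in steps of 0.2 and
#'   `beta` in `{0, 0.4, 0.6, 1}`.
#' @param warn_unstable Passed to [solve_crisp()].
#'
#' @return An object of class `fuzzy_solution`: a list of
#'   `crisp_solution`s indexed by an `(r, beta)` tibble.  [tidy()]
#'   returns the long `(r, beta, n, t, i, x, u)` table.
#' @export
solve_fuzzy <- function(fmodel, grid,
                        r_grid = seq(0, 1, by = 0.2),
                        beta_grid = c(0, 0.4, 0.6, 1),
                        warn_unstable = TRUE) {
  stopifnot(inherits(fmodel, "fuzzy_model_spec"), inherits(grid, "grid_spec"))
  if (length(r_grid) == 0 || length(beta_grid) == 0) {
    abort("r_grid and beta_grid must be non-empty.")
  }
  check_unit_interval(r_grid, "r_grid")
  check_unit_interval(beta_grid, "beta_grid")
  index <- tidyr::expand_grid(r = r_grid, beta = beta_grid)
  sols <- purrr::pmap(index, function(r, beta) {
    solve_crisp(at_sample(fmodel, r, beta), grid,
                warn_unstable = warn_unstable)
  })
  # only the first sample needs to warn; silence duplicates
  structure(
    list(solutions = sols, index = index, grid = grid, fmodel = fmodel),
    class = "fuzzy_solution"
  )
}

#' @export
print.fuzzy_solution <- function(x, ...) {
  cat(sprintf(
    "<fuzzy_solution %d (r, beta) samples on a %d x %d grid (alpha = %g)>\n",
    nrow(x$index), x$grid$N + 1L, x$grid$M + 1L, x$grid$alpha))
  invisible(x)
}

#' @rdname solution_at
#' @param r,beta Optional filters selecting samples of a fuzzy solution.
#' @export
solution_at.fuzzy_solution <- function(sol, x, t, r = NULL, beta = NULL, ...) {
  keep <- rep(TRUE, nrow(sol$index))
  if (!is.null(r)) keep <- keep & sol$index$r %in% r
  if (!is.null(beta)) keep <- keep & sol$index$beta %in% beta
  if (!any(keep)) abort("No (r, beta) sample matches the filter.")
  vals <- purrr::map_dbl(sol$solutions[keep],
                         function(s) solution_at(s, x, t))
  dplyr::mutate(sol$index[keep, ], x = x, t = t, u = vals)
}

#' @export
tidy.fuzzy_solution <- function(x, ...) {
  purrr::map2(seq_len(nrow(x$index)), x$solutions, function(k, s) {
    dplyr::mutate(tidy(s), r = x$index$r[k], beta = x$index$beta[k])
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("r", "beta", "n", "t", "i", "x", "u")
}

#' @export
glance.fuzzy_solution <- function(x, ...) {
  g <- x$grid
  rep0 <- x$solutions[[1L]]$stability
  tibble(
    n_samples = nrow(x$index),
    alpha = g$alpha, dx = g$dx, dt = g$dt,
    s = rep0$s, bound_prop1 = rep0$bound_prop1,
    stable_prop1 = rep0$stable_prop1
  )
}
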