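#' Space-time grid and fractional order
#'
#' Node-centered uniform discretization of the domain
#' `[0, L] x [0, t_end]`: space nodes `x_i = i * dx` for `i = 0..M` and
#' time levels `t_n = n * dt` for `n = 0..N`, with `M = L / dx` and
#' `N = t_end / dt` required to be whole numbers (within rounding
#' tolerance).  `alpha` is the Caputo fractional order of the time
#' derivative, restricted to `(0, 1]`; `alpha = 1` recovers the classical
#' forward-time scheme.
#'
#' @param L Domain length (space units).
#' @param t_end Final time.
#' @param dx Space step.
#' @param dt Time step.
#' @param alpha Fractional order in `(0, 1]`.
#'
#' @return An object of class `grid_spec` with derived fields `M` (number
#'   of space intervals) and `N` (number of time steps).
#' @examples
#' g <- grid_spec(L = 8, t_end = 0.05, dx = 0.5, dt = 0.01, alpha = 0.9)
#' x_nodes(g)
#' @export
grid_spec <- function(L, t_end, dx, dt, alpha) {
  stopifnot(is.numeric(L), is.numeric(t_end), is.numeric(dx),
            is.numeric(dt), is.numeric(alpha))
  if (alpha <= 0 || alpha > 1) abort("alpha must lie in (0, 1].")
  if (dx <= 0 || dt <= 0) abort("dx and dt must be positive.")
  if (L <= 0 || t_end <= 0) abort("L and t_end must be positive.")
  M <- L / dx
  N <- t_end / dt
  if (abs(M - round(M)) > 1e-8 * max(1, M)) {
    abort("L must be an integer multiple of dx.")
  }
  if (abs(N - round(N)) > 1e-8 * max(1, N)) {
    abort("t_end must be an integer multiple of dt.")
  }
  structure(
    list(L = L, t_end = t_end, dx = dx, dt = dt, alpha = alpha,
         M = as.integer(round(M)), N = as.integer(round(N))),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec [0, %g] x [0, %g]; dx = %g (M = %d), dt = %g (N = %d), alpha = %g>\n",
    x$L, x$t_end, x$dx, x$N * 0 + x$dt, x$N, x$alpha))
  invisible(x)
}

#' @rdname grid_spec
#' @param grid A `grid_spec`.
#' @export
x_nodes <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  (0:grid$M) * grid$dx
}

#' @rdname grid_spec
#' @export
t_levels <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  (0:grid$N) * grid$dt
}

# Map a requested coordinate to its node index (1-based); off-node
# coordinates are an error -- the solver never interpolates.
node_index <- function(value, step, n_max, what, tol = 1e-9) {
  idx <- value / step
  if (abs(idx - round(idx)) > tol / step) {
    abort(sprintf("%s = %g does not coincide with a grid node.", what, value))
  }
  idx <- as.integer(round(idx))
  if (idx < 0 || idx > n_max) {
    abort(sprintf("%s = %g lies outside the grid.", what, value))
  }
  idx + 1L
}
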