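#' Caputo memory weights
#'
#' The L1-type discretization of the Caputo derivative of order
#' `alpha` carries a memory of all past time levels through the weights
#' `b_j = (j + 1)^(1 - alpha) - j^(1 - alpha)`, `j = 1, 2, ...`.
#' They satisfy `0 < b_j <= 1`, are strictly decreasing, and with
#' `b_0 = 1` telescope as `sum_{j=0}^{n-1} (b_j - b_{j+1}) = 1 - b_n`.
#' At `alpha = 1` all weights vanish and the scheme loses its memory.
#'
#' @param alpha Fractional order in `(0, 1]`.
#' @param n_max Number of weights required (the run's number of time
#'   steps suffices).
#'
#' @return An object of class `caputo_weights`: numeric vector `b` of
#'   length `n_max` (`b[j]` is `b_j`) plus the order `alpha`.
#' @examples
#' caputo_weights(0.9, 5)$b[1]   # 2^0.1 - 1
#' @export
caputo_weights <- function(alpha, n_max) {
  stopifnot(is.numeric(alpha), length(alpha) == 1)
  if (alpha <= 0 || alpha > 1) abort("alpha must lie in (0, 1].")
  n_max <- as.integer(n_max)
  if (is.na(n_max) || n_max < 1) abort("n_max must be a positive integer.")
  j <- seq_len(n_max)
  structure(
    list(b = (j + 1)^(1 - alpha) - j^(1 - alpha), alpha = alpha),
    class = "caputo_weights"
  )
}

#' @export
print.caputo_weights <- function(x, ...) {
  cat(sprintf("<caputo_weights alpha = %g, n = %d; b_1 = %.6g>\n",
              x$alpha, length(x$b), x$b[1]))
  invisible(x)
}

#' Scheme coefficients
#'
#' The explicit update is governed by the reaction multiplier
#' `rho = dt^alpha * Gamma(2 - alpha)` and the fractional diffusion
#' number `s = rho / dx^2`.  `s` is the quantity bounded by the stability
#' conditions; at `alpha = 1` it reduces to the classical `dt / dx^2`.
#'
#' @param grid A [grid_spec()].
#'
#' @return An object of class `scheme_coefficients` with fields `s`,
#'   `rho` and `alpha`.
#' @examples
#' scheme_coefficients(grid_spec(8, 0.05, 0.5, 0.01, 0.9))$s  # ~0.0603
#' @export
scheme_coefficients <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  rho <- grid$dt^grid$alpha * gamma(2 - grid$alpha)
  structure(list(s = rho / grid$dx^2, rho = rho, alpha = grid$alpha),
            class = "scheme_coefficients")
}

#' @export
print.scheme_coefficients <- function(x, ...) {
  cat(sprintf("<scheme_coefficients s = %.6g, rho = %.6g (alpha = %g)>\n",
              x$s, x$rho, x$alpha))
  invisible(x)
}
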