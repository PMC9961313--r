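# Independent classical FTCS reference: forward-time centered-space update
#   u_i^{n+1} = u_i^n + s (u_{i+1}^n - 2 u_i^n + u_{i-1}^n) - dt k(x_i, t_n) u_i^n
# written as plain scalar loops, sharing no code with the package solver.
ftcs_reference <- function(ic_vals, dx, dt, N, k_fn = function(x, t) 0,
                           bc_left = function(t) 0, bc_right = function(t) 0) {
  M1 <- length(ic_vals)
  s <- dt / dx^2
  U <- matrix(0, N + 1, M1)
  U[1, ] <- ic_vals
  U[1, 1] <- bc_left(0)
  U[1, M1] <- bc_right(0)
  for (n in 1:N) {
    t_prev <- (n - 1) * dt
    U[n + 1, 1] <- bc_left(n * dt)
    U[n + 1, M1] <- bc_right(n * dt)
    for (i in 2:(M1 - 1)) {
      x_i <- (i - 1) * dx
      U[n + 1, i] <- U[n, i] +
        s * (U[n, i + 1] - 2 * U[n, i] + U[n, i - 1]) -
        dt * k_fn(x_i, t_prev) * U[n, i]
    }
  }
  U
}

# Random small crisp instance on [0, 1]: smooth random IC, random constant
# boundary data and a random (possibly t-dependent) killing rate.  The
# default grid keeps the fractional diffusion number inside the stability
# bound for the whole alpha range drawn.
random_instance <- function(seed, alpha = NULL,
                            grid_args = list(L = 1, t_end = 1e-3,
                                             dx = 0.2, dt = 1e-4)) {
  withr::with_seed(seed, {
    a <- runif(3, -1, 1)
    kc <- runif(1, 0, 2)
    k_kind <- sample(c("const", "time"), 1)
    alpha <- alpha %||% runif(1, 0.55, 1)
    list(
      model = fuzzyfdm::model_spec(
        ic = function(x) a[1] * sin(pi * x) + a[2] * x * (1 - x) + a[3],
        k_fn = if (k_kind == "const") function(x, t) rep(kc, length(x))
               else function(x, t) rep(kc * t, length(x)),
        bc_left = a[3], bc_right = a[3]
      ),
      alpha = alpha,
      grid = do.call(fuzzyfdm::grid_spec, c(grid_args, list(alpha = alpha)))
    )
  })
}
`%||%` <- function(x, y) if (is.null(x)) y else x

# Random populated history matrix for stepper-identity checks.
random_history <- function(seed, levels = 4, nodes = 5) {
  withr::with_seed(seed, {
    matrix(runif(levels * nodes, -1, 1), levels, nodes)
  })
}

expect_rel_equal <- function(actual, expected, tol = 1e-12) {
  scale <- pmax(abs(expected), 1e-300)
  expect_true(all(abs(actual - expected) / scale <= tol | actual == expected),
              label = sprintf("max rel diff %.3g within %.3g",
                              max(abs(actual - expected) / scale), tol))
}
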