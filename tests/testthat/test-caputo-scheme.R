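test_that("Caputo weights match direct evaluation and vanish at alpha = 1", {
  expect_equal(caputo_weights(1, 10)$b, rep(0, 10))
  expect_equal(caputo_weights(0.9, 5)$b[1], 2^0.1 - 1)
  expect_equal(caputo_weights(0.5, 5)$b[3], 2 - sqrt(3))
  expect_error(caputo_weights(0, 5), "alpha")
  expect_error(caputo_weights(1.2, 5), "alpha")
  expect_error(caputo_weights(0.5, 0), "n_max")
})

test_that("weights are positive, bounded by one, decreasing, and telescope", {
  for (alpha in seq(0.1, 0.9, by = 0.2)) {
    b <- caputo_weights(alpha, 100)$b
    expect_true(all(b > 0 & b <= 1))
    expect_true(all(diff(b) < 0))
    # with b_0 = 1: sum_{j=0}^{n-1} (b_j - b_{j+1}) = 1 - b_n
    b0 <- c(1, b)
    n <- length(b)
    expect_equal(sum(b0[1:n] - b0[2:(n + 1)]), 1 - b[n])
  }
})

test_that("scheme coefficients follow rho = dt^alpha Gamma(2 - alpha), s = rho / dx^2", {
  c1 <- scheme_coefficients(grid_spec(1, 0.05, 0.5, 0.01, alpha = 1))
  expect_equal(c1$s, 0.04)
  c2 <- scheme_coefficients(grid_spec(8, 0.05, 0.5, 0.01, alpha = 0.9))
  expect_equal(c2$s, 0.01^0.9 * gamma(1.1) / 0.25)
  expect_equal(c2$s, 0.06031157, tolerance = 1e-6)
  c3 <- scheme_coefficients(grid_spec(1, 0.05, 0.1, 0.01, alpha = 0.5))
  expect_equal(c3$s, 0.1 * gamma(1.5) / 0.01)
  expect_equal(c3$s, 8.862269, tolerance = 1e-6)
  expect_equal(c3$s, c3$rho / 0.1^2)
})

test_that("a single explicit step treats degenerate cases correctly", {
  grid <- grid_spec(2, 0.05, 0.5, 0.01, alpha = 0.7)
  coeff <- scheme_coefficients(grid)
  w <- caputo_weights(0.7, 5)
  zero_k <- function(x, t) rep(0, length(x))

  # spatially uniform field, no reaction: diffusion and memory vanish
  hist <- matrix(3.5, 1, grid$M + 1)
  expect_equal(explicit_step(hist, 0, coeff, w, zero_k, grid),
               rep(3.5, grid$M - 1))

  # alpha = 1: the step is exactly the classical FTCS update
  g1 <- grid_spec(1, 0.01, 0.1, 0.001, alpha = 1)
  c1 <- scheme_coefficients(g1)
  w1 <- caputo_weights(1, 10)
  u <- sin(pi * x_nodes(g1))
  hist1 <- rbind(u, u + 0.1)  # two arbitrary levels: memory must not enter
  int <- 2:g1$M
  ftcs <- u[int] + c1$s * (u[int + 1] - 2 * u[int] + u[int - 1])
  stepped <- explicit_step(rbind(u), 0, c1, w1, zero_k, g1)
  expect_equal(stepped, unname(ftcs))
  # with all b_j = 0 the same holds at a later level
  u2 <- hist1[2, ]
  ftcs2 <- u2[int] + c1$s * (u2[int + 1] - 2 * u2[int] + u2[int - 1])
  expect_equal(explicit_step(hist1, 1, c1, w1, zero_k, g1), unname(ftcs2))
})

test_that("one step from the exponential profile matches the direct closed form", {
  # IC e^(-x), alpha = 0.9, dx = 0.5, dt = 0.01, k(t) = t^2; at n = 0 the
  # memory is empty and k(0) = 0, so the step collapses to
  # u e^(-x) [1 + s (e^(1/2) + e^(-1/2) - 2)]
  grid <- grid_spec(8, 0.05, 0.5, 0.01, alpha = 0.9)
  coeff <- scheme_coefficients(grid)
  w <- caputo_weights(0.9, 5)
  k_fn <- function(x, t) rep(t^2, length(x))
  hist <- rbind(exp(-x_nodes(grid)))
  stepped <- explicit_step(hist, 0, coeff, w, k_fn, grid)
  i4 <- 8  # interior index of x = 4 (interior nodes start at x = 0.5)
  expected <- exp(-4) * (1 + coeff$s * (exp(0.5) + exp(-0.5) - 2))
  expect_equal(stepped[i4], expected)
  expect_equal(expected / exp(-4), 1.0153946, tolerance = 1e-7)
})

test_that("memory-sum and regrouped steppers are algebraically identical", {
  zero_k <- function(x, t) rep(0, length(x))
  for (seed in 1:8) {
    grid <- grid_spec(2, 0.04, 0.5, 0.01, alpha = 0.7)
    coeff <- scheme_coefficients(grid)
    w <- caputo_weights(0.7, 4)
    hist <- random_history(seed, levels = 4, nodes = grid$M + 1)
    k_fn <- function(x, t) rep(0.3 + 0.1 * t, length(x))
    for (n in 0:3) {
      a <- explicit_step(hist[1:(n + 1), , drop = FALSE], n, coeff, w, k_fn, grid)
      b <- explicit_step_regrouped(hist[1:(n + 1), , drop = FALSE], n, coeff, w, k_fn, grid)
      expect_rel_equal(b, a, tol = 1e-12)
    }
  }

  # n = 1: one memory term telescopes to -b_1 u^1 + b_1 u^0
  grid <- grid_spec(2, 0.04, 0.5, 0.01, alpha = 0.6)
  coeff <- scheme_coefficients(grid)
  w <- caputo_weights(0.6, 4)
  hist <- random_history(99, levels = 2, nodes = grid$M + 1)
  int <- 2:grid$M
  u1 <- hist[2, ]
  manual <- coeff$s * (u1[int + 1] + u1[int - 1]) +
    (1 - 2 * coeff$s - w$b[1]) * u1[int] + w$b[1] * hist[1, int]
  expect_equal(explicit_step_regrouped(hist, 1, coeff, w, zero_k, grid), manual)
  expect_rel_equal(explicit_step(hist, 1, coeff, w, zero_k, grid), manual)
})

test_that("stepping guards reject malformed inputs", {
  grid <- grid_spec(2, 0.04, 0.5, 0.01, alpha = 0.7)
  coeff <- scheme_coefficients(grid)
  w <- caputo_weights(0.7, 1)
  hist <- random_history(1, levels = 3, nodes = grid$M + 1)
  k0 <- function(x, t) rep(0, length(x))
  expect_error(explicit_step(hist, 2, coeff, w, k0, grid), "weights")
  expect_error(explicit_step(hist[, 1:3], 0, coeff, w, k0, grid), "columns")
  expect_error(explicit_step(hist[1, , drop = FALSE], 1, coeff, w, k0, grid),
               "populated")
})

test_that("crisp solver handles zero data, the heat benchmark, and linearity", {
  # identically-zero problem stays zero
  g <- grid_spec(1, 0.002, 0.1, 1e-4, alpha = 0.8)
  m0 <- model_spec(ic = function(x) rep(0, length(x)), k_fn = 1)
  expect_true(all(solve_crisp(m0, g)$u == 0))

  # classical heat benchmark
  gh <- grid_spec(1, 0.05, 0.1, 0.001, alpha = 1)
  mh <- model_spec(ic = function(x) sin(pi * x))
  sol <- solve_crisp(mh, gh)
  x <- x_nodes(gh)
  expect_lt(max(abs(sol$u[gh$N + 1, ] - classical_heat_exact(x, 0.05))), 5e-3)

  # linearity: scaling IC and BC scales the solution
  g2 <- grid_spec(1, 0.002, 0.1, 1e-4, alpha = 0.7)
  ic <- function(x) sin(pi * x) + 0.5
  m1 <- model_spec(ic = ic, k_fn = function(t) t, bc_left = 0.5, bc_right = 0.5)
  m3 <- model_spec(ic = function(x) 3 * ic(x), k_fn = function(t) t,
                   bc_left = 1.5, bc_right = 1.5)
  expect_rel_equal(solve_crisp(m3, g2)$u, 3 * solve_crisp(m1, g2)$u,
                   tol = 1e-12)
})

test_that("solution accessors insist on grid nodes and tidy to long form", {
  g <- grid_spec(1, 0.02, 0.1, 0.001, alpha = 0.9)
  sol <- solve_crisp(model_spec(ic = function(x) x * (1 - x)), g)
  expect_equal(solution_at(sol, 0.5, 0), 0.25)
  expect_error(solution_at(sol, 0.55, 0), "node")
  expect_error(solution_at(sol, 0.5, 0.0205), "node")

  td <- tidy(sol)
  expect_equal(nrow(td), (g$N + 1) * (g$M + 1))
  expect_named(td, c("n", "t", "i", "x", "u"))
  expect_equal(td$u[td$n == 0 & td$i == 5], 0.25)
  gl <- glance(sol)
  expect_true(gl$stable_prop1)
})

test_that("fuzzy solves reduce to scaled crisp runs for the worked example", {
  cfg <- preset_worked_example()
  bundle <- solve_fuzzy(cfg$model, cfg$grid, r_grid = c(0, 0.5, 1),
                        beta_grid = c(0, 1))

  # r = 1: phi = 0, so the whole field vanishes for any beta
  at_core <- solution_at(bundle, 4, 0.05, r = 1)
  expect_identical(at_core$u, rep(0, nrow(at_core)))

  # the upper branch is the exact negative of the lower branch
  lo <- bundle$solutions[[which(bundle$index$r == 0 & bundle$index$beta == 0)]]
  up <- bundle$solutions[[which(bundle$index$r == 0 & bundle$index$beta == 1)]]
  expect_identical(up$u, -lo$u)

  expect_error(solve_fuzzy(cfg$model, cfg$grid, r_grid = numeric(0)),
               "non-empty")
})

test_that("crisp-degenerate fuzzy scales reproduce the crisp solver", {
  one <- tri_fuzzy(1, 1, 1)
  g <- grid_spec(1, 0.002, 0.1, 1e-4, alpha = 0.8)
  fm <- fuzzy_model_spec(
    ic = fuzzy_field(one, function(x) sin(pi * x)),
    k = fuzzy_field(one, function(x, t) rep(0.5, length(x))),
    bc_left = 0, bc_right = 0)
  bundle <- solve_fuzzy(fm, g, r_grid = c(0, 0.5, 1), beta_grid = c(0, 1))
  crisp <- solve_crisp(model_spec(ic = function(x) sin(pi * x), k_fn = 0.5), g)
  for (sol in bundle$solutions) expect_identical(sol$u, crisp$u)
})
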