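as_tfun <- function(f, what) {
  if (is.numeric(f) && length(f) == 1) {
    val <- f
    return(function(t) rep(val, length(t)))
  }
  if (!is.function(f)) abort(sprintf("`%s` must be a constant or a function of t.", what))
  f
}

#' Crisp reaction-diffusion model specification
#'
#' One crisp instance of the tumor model
#' `d^alpha u / dt^alpha = d^2 u / dx^2 - k(x, t) u` on `[0, L]` with
#' Dirichlet boundary data.  Fuzzy problems reduce to a family of these
#' via [at_sample()] / [solve_fuzzy()].
#'
#' @param ic Initial condition: a function of `x` (vectorized) giving
#'   `u(x, 0)`.
#' @param k_fn Net killing rate `k(x, t)`: function of `(x, t)`, a
#'   function of one argument (interpreted as `t` alone, the validated
#'   case), or a constant.
#' @param bc_left,bc_right Dirichlet boundary values at `x = 0` and
#'   `x = L`: constants or functions of `t`.
#' @param boundary_mode Descriptive tag retained on solutions
#'   (`"fixed-value"`, `"function"` or `"from-oracle"`).
#'
#' @return An object of class `model_spec`.
#' @examples
#' m <- model_spec(ic = function(x) sin(pi * x), k_fn = 0,
#'                 bc_left = 0, bc_right = 0)
#' @export
model_spec <- function(ic, k_fn = 0, bc_left = 0, bc_right = 0,
                       boundary_mode = NULL) {
  if (!is.function(ic)) abort("`ic` must be a function of x.")
  if (is.numeric(k_fn) && length(k_fn) == 1) {
    kval <- k_fn
    k_fn <- function(x, t) rep(kval, length(x))
  } else if (is.function(k_fn) && length(formals(k_fn)) == 1) {
    kt <- k_fn
    k_fn <- function(x, t) rep(kt(t), length(x))
  } else if (!is.function(k_fn)) {
    abort("`k_fn` must be a function or a constant.")
  }
  mode <- boundary_mode %||%
    if (is.numeric(bc_left) && is.numeric(bc_right)) "fixed-value" else "function"
  structure(
    list(ic = ic, k_fn = k_fn,
         bc_left = as_tfun(bc_left, "bc_left"),
         bc_right = as_tfun(bc_right, "bc_right"),
         boundary_mode = mode),
    class = "model_spec"
  )
}

#' Fuzzy reaction-diffusion model specification
#'
#' The fuzzy model carries its uncertain data as [fuzzy_field()]s (fuzzy
#' scale times crisp kernel) for the initial condition and the killing
#' rate, and fuzzy Dirichlet boundary values.  Under the double
#' parametric form, evaluating every field at a sample
#' `(r, beta) in [0,1]^2` yields a crisp [model_spec()]; sweeping the
#' sample grid yields the fuzzy solution band.
#'
#' @param ic A [fuzzy_field()] whose kernel depends on `x` only.
#' @param k A [fuzzy_field()] for the killing rate, or a crisp function /
#'   constant (wrapped with a degenerate scale).
#' @param bc_left,bc_right Fuzzy boundary data: a function
#'   `(t, r, beta) -> value`, a [tri_fuzzy()] constant-in-time value, or
#'   a crisp constant.
#' @param boundary_mode Optional descriptive tag (see [model_spec()]).
#'
#' @return An object of class `fuzzy_model_spec`.
#' @export
fuzzy_model_spec <- function(ic, k = 0, bc_left = 0, bc_right = 0,
                             boundary_mode = NULL) {
  stopifnot(inherits(ic, "fuzzy_field"))
  crisp_one <- tri_fuzzy(1, 1, 1)
  if (!inherits(k, "fuzzy_field")) {
    if (is.numeric(k) && length(k) == 1) {
      kval <- k
      k <- fuzzy_field(crisp_one, function(x, t) rep(kval, length(x)))
    } else if (is.function(k)) {
      kf <- if (length(formals(k)) == 1) {
        kt <- k
        function(x, t) rep(kt(t), length(x))
      } else k
      k <- fuzzy_field(crisp_one, kf)
    } else {
      abort("`k` must be a fuzzy_field, a function or a constant.")
    }
  }
  as_fuzzy_bc <- function(b, what) {
    if (inherits(b, "tri_fuzzy")) {
      function(t, r, beta) rep(double_param_value(b, r, beta), length(t))
    } else if (is.numeric(b) && length(b) == 1) {
      function(t, r, beta) rep(b, length(t))
    } else if (is.function(b) && length(formals(b)) == 3) {
      b
    } else {
      abort(sprintf("`%s` must be a (t, r, beta) function, tri_fuzzy or constant.", what))
    }
  }
  structure(
    list(ic = ic, k = k,
         bc_left = as_fuzzy_bc(bc_left, "bc_left"),
         bc_right = as_fuzzy_bc(bc_right, "bc_right"),
         boundary_mode = boundary_mode %||% "function"),
    class = "fuzzy_model_spec"
  )
}

#' Crisp instance of a fuzzy model at an (r, beta) sample
#'
#' @param fmodel A [fuzzy_model_spec()].
#' @param r,beta The double parametric sample, each in `[0, 1]`.
#' @return A crisp [model_spec()] whose data are the fuzzy fields
#'   evaluated at `(r, beta)`.
#' @export
at_sample <- function(fmodel, r, beta) {
  stopifnot(inherits(fmodel, "fuzzy_model_spec"))
  check_unit_interval(r, "r")
  check_unit_interval(beta, "beta")
  ic_fn <- fuzzify_field(fmodel$ic, r, beta)
  k_fn <- fuzzify_field(fmodel$k, r, beta)
  bl <- fmodel$bc_left
  br <- fmodel$bc_right
  model_spec(
    ic = function(x) ic_fn(x, 0),
    k_fn = k_fn,
    bc_left = function(t) bl(t, r, beta),
    bc_right = function(t) br(t, r, beta),
    boundary_mode = fmodel$boundary_mode
  )
}
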