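#' Triangular fuzzy number
#'
#' A triangular fuzzy number is defined by its support `[left, right]` and
#' its core (the single point with membership 1).  Membership rises linearly
#' from `left` to `core` and falls linearly from `core` to `right`.  All
#' fuzzy scales in this package (initial-condition scale, killing-rate
#' scale, fuzzy boundary values) are triangular; the symmetric scale
#' `tri_fuzzy(-1, 0, 1)` is the one used by the validated worked example.
#'
#' @param left Left endpoint of the support.
#' @param core Point of membership 1.
#' @param right Right endpoint of the support.
#'
#' @return An object of class `tri_fuzzy`.
#' @examples
#' phi <- tri_fuzzy(-1, 0, 1)
#' r_cut(phi, c(0, 0.5, 1))
#' @export
tri_fuzzy <- function(left, core, right) {
  stopifnot(is.numeric(left), is.numeric(core), is.numeric(right),
            length(left) == 1, length(core) == 1, length(right) == 1)
  if (!is.finite(left) || !is.finite(core) || !is.finite(right)) {
    abort("tri_fuzzy endpoints must be finite.")
  }
  if (left > core || core > right) {
    abort("tri_fuzzy requires left <= core <= right.")
  }
  structure(list(left = as.numeric(left), core = as.numeric(core),
                 right = as.numeric(right)),
            class = "tri_fuzzy")
}

#' @export
print.tri_fuzzy <- function(x, ...) {
  cat(sprintf("<tri_fuzzy (%g, %g, %g)>\n", x$left, x$core, x$right))
  invisible(x)
}

#' @export
format.tri_fuzzy <- function(x, ...) {
  sprintf("(%g, %g, %g)", x$left, x$core, x$right)
}

is_tri_fuzzy <- function(x) inherits(x, "tri_fuzzy")

#' Is a triangular fuzzy number crisp?
#'
#' A degenerate triangular number with `left == core == right` behaves as a
#' crisp scalar: every r-cut is the single point `core`.
#'
#' @param fz A [tri_fuzzy()] object.
#' @return `TRUE` if all three defining points coincide.
#' @export
is_crisp <- function(fz) {
  stopifnot(is_tri_fuzzy(fz))
  fz$left == fz$core && fz$core == fz$right
}

check_unit_interval <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be numeric in [0, 1].", name))
  }
  invisible(x)
}

#' r-level cut of a triangular fuzzy number
#'
#' The r-cut is the interval of values with membership at least `r`.  For a
#' triangular number the cuts are linear in `r`:
#' `lower(r) = left + r (core - left)` and
#' `upper(r) = right - r (right - core)`, so `r = 0` recovers the support
#' and `r = 1` collapses to the core.
#'
#' @param fz A [tri_fuzzy()] object.
#' @param r Membership level(s) in `[0, 1]`; vectorized.
#'
#' @return A tibble with columns `r`, `lower`, `upper`, one row per level.
#' @examples
#' r_cut(tri_fuzzy(-1, 0, 1), 0.4)   # [-0.6, 0.6]
#' @export
r_cut <- function(fz, r) {
  stopifnot(is_tri_fuzzy(fz))
  check_unit_interval(r, "r")
  tibble(
    r     = r,
    lower = fz$left + r * (fz$core - fz$left),
    upper = fz$right - r * (fz$right - fz$core)
  )
}

#' Double parametric value of a triangular fuzzy number
#'
#' Collapses the interval pair `[lower(r), upper(r)]` into one scalar family
#' `value = beta * (upper(r) - lower(r)) + lower(r)` over
#' `(r, beta) in [0,1]^2`.  `beta = 0` gives the lower branch, `beta = 1`
#' the upper; at `r = 1` every `beta` returns the core.  For the symmetric
#' scale `(-1, 0, 1)` this is `beta (2 - 2 r) + (r - 1)`.
#'
#' @inheritParams r_cut
#' @param beta Branch parameter(s) in `[0, 1]`; recycled against `r`.
#'
#' @return A numeric vector of crisp representative values.
#' @examples
#' double_param_value(tri_fuzzy(-1, 0, 1), r = 0, beta = c(0, 0.5, 1))
#' @export
double_param_value <- function(fz, r, beta) {
  stopifnot(is_tri_fuzzy(fz))
  check_unit_interval(r, "r")
  check_unit_interval(beta, "beta")
  n <- max(length(r), length(beta))
  r <- rep_len(r, n)
  beta <- rep_len(beta, n)
  cut <- r_cut(fz, r)
  out <- beta * (cut$upper - cut$lower) + cut$lower
  # the branch endpoints are exact, not reconstructed through arithmetic
  out[beta == 0] <- cut$lower[beta == 0]
  out[beta == 1] <- cut$upper[beta == 1]
  out
}

#' Fuzzy coefficient field
#'
#' The model's fuzzy coefficients factor as a fuzzy scale times a crisp
#' kernel: the killing rate is `scale1 * s1(x, t)` and the initial
#' condition `scale2 * s2(x)`.  A `fuzzy_field` stores that pair;
#' [fuzzify_field()] evaluates it at an `(r, beta)` sample, returning a
#' crisp function of `(x, t)`.
#'
#' @param scale A [tri_fuzzy()] scale.
#' @param kernel A crisp function `f(x, t)` (functions of `x` alone are
#'   accepted and wrapped).
#'
#' @return An object of class `fuzzy_field`.
#' @examples
#' f <- fuzzy_field(tri_fuzzy(-1, 0, 1), function(x, t) exp(-x))
#' g <- fuzzify_field(f, r = 0, beta = 1)
#' g(0, 0)  # 1
#' @export
fuzzy_field <- function(scale, kernel) {
  stopifnot(is_tri_fuzzy(scale), is.function(kernel))
  if (length(formals(kernel)) == 1) {
    inner <- kernel
    kernel <- function(x, t) inner(x)
  }
  structure(list(scale = scale, kernel = kernel), class = "fuzzy_field")
}

#' @export
print.fuzzy_field <- function(x, ...) {
  cat(sprintf("<fuzzy_field scale %s x crisp kernel>\n",
              format(x$scale)))
  invisible(x)
}

#' Evaluate a fuzzy field at an (r, beta) sample
#'
#' @param field A [fuzzy_field()], or a [tri_fuzzy()] scale together with
#'   `kernel`.
#' @param r,beta The double parametric sample, each in `[0, 1]`.
#' @param kernel Crisp kernel when `field` is given as a bare scale.
#'
#' @return A crisp function `g(x, t)` with
#'   `g(x, t) = double_param_value(scale, r, beta) * kernel(x, t)`.
#' @export
fuzzify_field <- function(field, r, beta, kernel = NULL) {
  if (is_tri_fuzzy(field)) field <- fuzzy_field(field, kernel)
  stopifnot(inherits(field, "fuzzy_field"))
  phi <- double_param_value(field$scale, r, beta)
  stopifnot(length(phi) == 1)
  k <- field$kernel
  function(x, t) phi * k(x, t)
}

#' Validate a fuzzy solution band
#'
#' Checks that lower/upper branch values computed over an r grid form a
#' valid fuzzy band: `lower <= upper` pointwise and, when `r` is supplied,
#' nesting in `r` (lower nondecreasing, upper nonincreasing as `r` grows).
#'
#' @param lower_values,upper_values Numeric vectors of equal length, branch
#'   values over an r grid.
#' @param r Optional r grid (same length) enabling the nesting check; must
#'   be sorted increasing.
#' @param tol Numerical slack for the comparisons.
#'
#' @return `TRUE` or `FALSE`.
#' @export
band_is_valid <- function(lower_values, upper_values, r = NULL,
                          tol = 1e-12) {
  if (length(lower_values) != length(upper_values)) {
    abort("lower_values and upper_values must have equal length.")
  }
  if (!all(lower_values <= upper_values + tol)) return(FALSE)
  if (!is.null(r)) {
    if (length(r) != length(lower_values)) {
      abort("r must match the band length.")
    }
    if (is.unsorted(r)) abort("r grid must be sorted increasing.")
    if (any(diff(lower_values) < -tol)) return(FALSE)
    if (any(diff(upper_values) > tol)) return(FALSE)
  }
  TRUE
}

#' Serialize / deserialize a triangular fuzzy number
#'
#' Round-trips a [tri_fuzzy()] through the JSON object
#' `{"left": l, "core": c, "right": r}` so fuzzy scales can live in run
#' configs.
#'
#' @param fz A [tri_fuzzy()] object.
#' @param json A JSON string or a list with fields `left`, `core`, `right`.
#' @return `tri_fuzzy_to_json()` returns a JSON string;
#'   `tri_fuzzy_from_json()` a [tri_fuzzy()].
#' @export
tri_fuzzy_to_json <- function(fz) {
  stopifnot(is_tri_fuzzy(fz))
  jsonlite::toJSON(unclass(fz), auto_unbox = TRUE, digits = NA)
}

#' @rdname tri_fuzzy_to_json
#' @export
tri_fuzzy_from_json <- function(json) {
  obj <- if (is.character(json)) jsonlite::fromJSON(json) else json
  if (!all(c("left", "core", "right") %in% names(obj))) {
    abort("Expected fields left, core, right.")
  }
  tri_fuzzy(obj$left, obj$core, obj$right)
}
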