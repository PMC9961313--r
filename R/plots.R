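#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   facet_wrap labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a crisp solution as space profiles over time
#'
#' @param object A `crisp_solution`.
#' @param ... Unused.
#' @return A ggplot: `u` against `x`, one line per time level.
#' @export
autoplot.crisp_solution <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$x, y = .data$u,
                 colour = .data$t, group = .data$t)) +
    geom_line() +
    labs(x = "x", y = "u(x, t)", colour = "t",
         title = sprintf("Explicit Caputo scheme (alpha = %g)",
                         object$grid$alpha)) +
    theme_minimal()
}

#' Plot a fuzzy solution band at one space-time node
#'
#' Reproduces the worked example's band view: the solution at a node
#' against the membership level `r`, one line per `beta`, showing the
#' triangular band collapsing to the core at `r = 1`.
#'
#' @param object A `fuzzy_solution`.
#' @param x,t Node to display (defaults to the worked example's
#'   `x = 4`, `t = 0.05`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fuzzy_solution <- function(object, x = 4, t = 0.05, ...) {
  df <- solution_at(object, x, t)
  ggplot(df, aes(x = .data$r, y = .data$u,
                 colour = factor(.data$beta), group = .data$beta)) +
    geom_line() +
    geom_point() +
    labs(x = "membership level r", y = sprintf("u(%g, %g; r, beta)", x, t),
         colour = "beta",
         title = "Fuzzy solution band (double parametric form)") +
    theme_minimal()
}

#' Plot perturbation-probe norm ratios
#'
#' @param object A `perturbation_probe`.
#' @param ... Unused.
#' @return A ggplot of `||eps^n|| / ||eps^0||` against the time level,
#'   with the no-growth reference line at 1.
#' @export
autoplot.perturbation_probe <- function(object, ...) {
  ggplot(object$ratios, aes(x = .data$n, y = .data$norm_ratio)) +
    geom_line() +
    geom_point() +
    geom_hline(yintercept = 1, linetype = "dashed") +
    labs(x = "time level n", y = "||eps^n|| / ||eps^0||",
         title = sprintf("Perturbation probe (s = %.3g, bound %.3g)",
                         object$stability$s,
                         object$stability$bound_prop1)) +
    theme_minimal()
}

#' Plot a numerical-vs-exact error table
#'
#' @param table A tibble from [abs_error_table()] or [run_error_table()].
#' @return A ggplot of the absolute error against `r`, faceted by
#'   `beta`.
#' @export
plot_error_table <- function(table) {
  stopifnot(all(c("r", "beta", "abs_error") %in% names(table)))
  ggplot(table, aes(x = .data$r, y = .data$abs_error)) +
    geom_line() +
    geom_point() +
    facet_wrap(~beta, labeller = "label_both") +
    labs(x = "membership level r", y = "|numerical - exact|",
         title = "Absolute error of the explicit scheme") +
    theme_minimal()
}
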