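#' Plot segment counts per order with the branching-ratio fit
#'
#' Log segment count against truncated Strahler order with the fitted
#' exponential decay line; the negated reciprocal slope is the branching
#' ratio.
#'
#' @param fit A [fit_branching_ratio()] result.
#' @return A ggplot object.
#' @export
plot_order_counts <- function(fit) {
  df <- fit$residuals
  ggplot2::ggplot(df, ggplot2::aes(x = .data$order, y = .data$n)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Truncated Strahler order", y = "Segments (log scale)",
      title = sprintf("Branching ratio gamma = %.3f", fit$gamma)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_order_counts
#' @param object A `branching_fit`.
#' @param ... Unused.
#' @export
autoplot.branching_fit <- function(object, ...) plot_order_counts(object)

#' Plot the radial scaling fit
#'
#' Log radius against log downstream endpoint count with the standard
#' major axis line; the slope is the radial scaling exponent, with
#' Murray's law (1/3) and the large-vessel WBE prediction (0.5) as
#' reference slopes.
#'
#' @param object A [radial_scaling_exponent()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scaling_fit <- function(object, ...) {
  df <- object$pairs
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_downstream, y = .data$radius)) +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::geom_abline(
      slope = object$exponent, intercept = object$intercept,
      colour = "purple"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Downstream endpoints", y = expression(Radius ~ (mu * m)),
      title = sprintf(
        "a = %.3f (95%% CI %.3f-%.3f)",
        object$exponent, object$ci[1L], object$ci[2L]
      )
    ) +
    ggplot2::theme_minimal()
}

#' Murray's-law plot
#'
#' Cubed parent radius against summed cubed child radii per junction, with
#' the Murray optimum (identity line) overlaid.
#'
#' @param murray A [murray_table()] result.
#' @return A ggplot object.
#' @export
plot_murray <- function(murray) {
  ggplot2::ggplot(murray, ggplot2::aes(x = .data$parent_cubed, y = .data$children_cubed)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "orange", linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = expression(r[parent]^3 ~ (mu * m^3)),
      y = expression(sum(r[child]^3) ~ (mu * m^3)),
      title = "Murray's law"
    ) +
    ggplot2::theme_minimal()
}
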