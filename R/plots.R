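#' Plot a cost-effectiveness plane
#'
#' Scatter of the bootstrapped incremental (effect, cost) pairs with the
#' origin axes and the full-sample point estimate highlighted.
#'
#' @param object A [bootstrap_contrasts()] draw set.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cea_draws <- function(object, ...) {
  pt <- attr(object, "point_estimate")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$delta_effect,
                                            y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, colour = "grey30", size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "Incremental effect (IG - CG)",
      y = "Incremental cost (€, IG - CG)",
      title = "Cost-effectiveness plane"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(pt)) {
    p <- p + ggplot2::annotate("point", x = pt[["delta_effect"]],
                               y = pt[["delta_cost"]],
                               colour = "red", size = 2.5)
  }
  p
}

#' @rdname autoplot.cea_draws
#' @param draws A `cea_draws` object.
#' @export
plot_ce_plane <- function(draws, ...) autoplot(draws, ...)

#' Plot a cost-effectiveness acceptability curve
#'
#' Probability of cost-effectiveness against willingness to pay.
#'
#' @param object A [ceac()] curve (several can be row-bound with a `label`
#'   column to overlay analyses).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ceac_curve <- function(object, ...) {
  aes <- if ("label" %in% names(object)) {
    ggplot2::aes(x = .data$wtp, y = .data$probability, colour = .data$label)
  } else {
    ggplot2::aes(x = .data$wtp, y = .data$probability)
  }
  ggplot2::ggplot(object, aes) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay (€ per effect unit)",
      y = "Probability cost-effective",
      title = "Cost-effectiveness acceptability curve"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ceac_curve
#' @param curve A `ceac_curve` object.
#' @export
plot_ceac <- function(curve, ...) autoplot(curve, ...)
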