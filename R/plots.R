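#' Plot observed and predicted pulse pressure against filling time
#'
#' The standard visual check of a fit: the observed pulse-pressure /
#' filling-time scatter overlaid with the fitted model curve (for the
#' expanded model, the curve is drawn at the median prepreceding interval).
#' A saturating shape with a visible plateau is the signature of an
#' identifiable stiffness; a straight line indicates the degenerate linear
#' regime.
#'
#' @param object An `lvstiff_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lvstiff_fit <- function(object, ...) {
  data <- object$data
  grid <- tibble::tibble(
    t_dia = seq(min(data$t_dia), max(data$t_dia), length.out = 200))
  if (object$model == "expanded") {
    grid$t_dia_prev <- stats::median(data$t_dia_prev, na.rm = TRUE)
    grid$pp_hat <- predict_pp_expanded(grid$t_dia, grid$t_dia_prev,
                                       object$params)
  } else {
    grid$pp_hat <- predict_pp_simple(grid$t_dia, object$params)
  }
  ggplot2::ggplot(data, ggplot2::aes(x = .data$t_dia, y = .data$pp)) +
    ggplot2::geom_point(alpha = 0.4, colour = "darkgreen") +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$pp_hat), colour = "firebrick",
                       linewidth = 1) +
    ggplot2::labs(
      x = "filling interval (s)", y = "pulse pressure (mmHg)",
      title = sprintf("%s model: FVE = %.2f, beta = %.3g /ml",
                      object$model, object$fve, object$params[["beta"]])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Residual panels of a stiffness fit
#'
#' Residuals against filling interval, prepreceding interval, and observed
#' pulse pressure, one facet per pairing, with least-squares trend lines.
#' A trend in the prepreceding-interval panel of a simple-model fit is the
#' signature the expanded model is designed to remove.
#'
#' @param fit An `lvstiff_fit`.
#' @return A ggplot object.
#' @export
plot_residuals <- function(fit) {
  rd <- residual_diagnostics(fit)
  long <- tidyr::unnest(rd[, c("pairing", "residual_data")],
                        "residual_data")
  long$pairing <- factor(long$pairing,
                         levels = c("t_dia", "t_dia_prev", "pp"),
                         labels = c("filling interval (s)",
                                    "prepreceding interval (s)",
                                    "observed PP (mmHg)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$resid)) +
    ggplot2::geom_point(alpha = 0.35) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick") +
    ggplot2::facet_wrap(~pairing, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "residual (mmHg)") +
    ggplot2::theme_minimal()
}
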