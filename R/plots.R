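#' Bland-Altman plot
#'
#' Scatter of per-unit differences against pairwise means with horizontal
#' reference lines at the bias and the 95% limits of agreement; optionally a
#' linear trend of difference on mean, whose slope is negative under
#' temperature-dependent bias.
#'
#' @param object A [bland_altman()] object.
#' @param trend Add a least-squares trend line of diff on mean.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bland_altman <- function(object, trend = FALSE, ...) {
  p <- ggplot2::ggplot(object$points, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(
      x = "Mean of devices (°C)",
      y = "Difference, test − reference (°C)",
      title = sprintf("Bland–Altman (%s): bias %.2f °C, LoA [%.2f, %.2f] °C",
                      object$round, object$bias, object$loa_lower,
                      object$loa_upper)
    ) +
    ggplot2::theme_minimal()
  if (trend) {
    p <- p + ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                                  se = FALSE, colour = "grey40")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
plot.bland_altman <- function(x, ...) print(autoplot(x, ...))

#' Calibration suite comparison plot
#'
#' MAE and RMSE per model from the out-of-fold metrics table.
#'
#' @param object A `"calibration_suite"` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration_suite <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::select("model", "mae", "rmse") |>
    tidyr::pivot_longer(c("mae", "rmse"), names_to = "metric",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = stats::reorder(.data$model, .data$value),
                                     y = .data$value, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Error (°C)",
                  title = "Cross-validated calibration error by model") +
    ggplot2::theme_minimal()
}
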