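#' Plot a psychometric fit
#'
#' Observed proportions of "comparison longer" per level with the fitted
#' cumulative normal and the PSE marked.
#'
#' @param object A `psychometric_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psychometric_fit
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  agg <- dplyr::mutate(object$data, p = .data$k / .data$n)
  xs <- seq(min(agg$comparison_ms), max(agg$comparison_ms), length.out = 200)
  curve <- tibble::tibble(
    comparison_ms = xs,
    p = object$lapse / 2 +
      (1 - object$lapse) * pnorm((xs - object$pse_ms) / object$sigma_ms)
  )
  ggplot2::ggplot(agg, ggplot2::aes(.data$comparison_ms, .data$p)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = object$pse_ms, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted", colour = "grey70") +
    ggplot2::labs(
      x = "Comparison duration (ms)",
      y = "P(comparison judged longer)",
      title = sprintf("PSE %.0f ms, WF %.3f", object$pse_ms, object$weber_fraction)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a central-tendency fit
#'
#' Trial scatter with the OLS line; the dashed identity marks veridical
#' reproduction, so the gap between the two lines visualizes the attraction
#' toward the mean duration.
#'
#' @param object A `central_tendency_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot central_tendency_fit
#' @export
autoplot.central_tendency_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data$stimulus_ms, .data$reproduced_ms)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept_ms,
                         colour = "firebrick") +
    ggplot2::labs(
      x = "Stimulus duration (ms)", y = "Reproduced duration (ms)",
      title = sprintf("Central tendency: slope %.2f", object$slope)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an architecture prediction
#'
#' Predicted reproduction means against the stimulus durations, with the
#' identity line for reference.
#'
#' @param object A `model_prediction`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot model_prediction
#' @export
autoplot.model_prediction <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(.data$stimulus_ms, .data$predicted_mean_ms)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Stimulus duration (ms)", y = "Predicted reproduction (ms)",
      title = sprintf("%s: predicted AV slope %.3f",
                      object$architecture, object$predicted_av_slope)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a prediction-vs-measurement regression
#'
#' @param object A `prediction_regression`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prediction_regression
#' @export
autoplot.prediction_regression <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$predicted, .data$measured)) +
    ggplot2::geom_ribbon(
      data = object$band,
      ggplot2::aes(x = .data$predicted, ymin = .data$lwr, ymax = .data$upr),
      inherit.aes = FALSE, alpha = 0.2
    ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_line(
      data = object$band,
      ggplot2::aes(x = .data$predicted, y = .data$fit),
      inherit.aes = FALSE, colour = "firebrick"
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Predicted", y = "Measured",
      title = sprintf("slope %.2f, r = %.2f", object$slope, object$r)
    ) +
    ggplot2::theme_minimal()
}

#' Central-tendency vs Weber-fraction curve families
#'
#' Plots predicted slope against Weber fraction for a set of prior widths;
#' darker curves are narrower priors (stronger central tendency), and
#' observed condition points can be overlaid.
#'
#' @param curves Output of [ct_wf_curve()].
#' @param points Optional tibble of observed `(wf, ct_slope)` points with an
#'   optional `label` column.
#' @return A ggplot object.
#' @export
plot_ct_wf_curves <- function(curves, points = NULL) {
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(.data$wf, .data$ct_slope,
                                    group = .data$prior_sd_ms,
                                    colour = .data$prior_sd_ms)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_gradient(low = "grey10", high = "grey75",
                                   name = "Prior width (ms)") +
    ggplot2::labs(x = "Weber fraction", y = "Central-tendency slope") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(
      data = points,
      ggplot2::aes(.data$wf, .data$ct_slope),
      inherit.aes = FALSE, size = 2
    )
  }
  p
}
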