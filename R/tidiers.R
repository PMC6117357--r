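#' Tidy a psychometric fit
#'
#' @param x A `psychometric_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`pse_ms`, `sigma_ms`,
#'   `weber_fraction`).
#' @method tidy psychometric_fit
#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(
    term = c("pse_ms", "sigma_ms", "weber_fraction"),
    estimate = c(x$pse_ms, x$sigma_ms, x$weber_fraction)
  )
}

#' Glance at a psychometric fit
#'
#' @inheritParams tidy.psychometric_fit
#' @return A one-row tibble with fit-level summaries.
#' @method glance psychometric_fit
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(
    pse_ms = x$pse_ms,
    sigma_ms = x$sigma_ms,
    weber_fraction = x$weber_fraction,
    n_trials = x$n_trials,
    loglik = x$loglik,
    converged = x$converged
  )
}

#' Tidy a central-tendency fit
#'
#' @param x A `central_tendency_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter.
#' @method tidy central_tendency_fit
#' @export
tidy.central_tendency_fit <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept_ms", "overall_bias_ms"),
    estimate = c(x$slope, x$intercept_ms, x$overall_bias_ms)
  )
}

#' Glance at a central-tendency fit
#'
#' @inheritParams tidy.central_tendency_fit
#' @return A one-row tibble with fit-level summaries.
#' @method glance central_tendency_fit
#' @export
glance.central_tendency_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope,
    intercept_ms = x$intercept_ms,
    overall_bias_ms = x$overall_bias_ms,
    n_used = x$n_used,
    n_excluded = x$n_excluded,
    r2 = x$r2
  )
}

#' Tidy an architecture prediction
#'
#' @param x A `model_prediction` object.
#' @param ... Unused.
#' @return The per-duration prediction tibble with the architecture label.
#' @method tidy model_prediction
#' @export
tidy.model_prediction <- function(x, ...) {
  dplyr::mutate(x$predictions, architecture = x$architecture, .before = 1)
}

#' Glance at an architecture prediction
#'
#' @inheritParams tidy.model_prediction
#' @return A one-row tibble with the predicted slope and Weber fraction.
#' @method glance model_prediction
#' @export
glance.model_prediction <- function(x, ...) {
  tibble::tibble(
    architecture = x$architecture,
    predicted_av_slope = x$predicted_av_slope,
    predicted_av_wf = x$predicted_av_wf
  )
}

#' Tidy a prediction-vs-measurement regression
#'
#' @param x A `prediction_regression` object.
#' @param ... Unused.
#' @return A one-row tibble with slope, intercept, correlation and n.
#' @method tidy prediction_regression
#' @export
tidy.prediction_regression <- function(x, ...) {
  tibble::tibble(
    slope = x$slope,
    intercept = x$intercept,
    r = x$r,
    r_p_value = x$r_p_value,
    n = x$n
  )
}
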