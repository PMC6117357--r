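#' Parameters of the generative Bayesian observer
#'
#' The observer measures a duration `D` with Gaussian sensory noise whose
#' width follows the scalar property, `sigma_L = WF * D` (Weber fraction `WF`
#' per modality and noise level), and combines the measurement with a Gaussian
#' prior over durations centered on the mean presented duration. The posterior
#' mean drives reproduction; discrimination responses arise from the same
#' scalar noise. For audiovisual stimuli the architecture decides the order of
#' integration:
#'
#' * `"model1"`: each modality's measurement is biased by its own prior first,
#'   then the two biased estimates are combined by reliability-weighted
#'   averaging (maximum-likelihood estimation, MLE) using the posterior widths.
#' * `"model2"`: the two unbiased measurements are MLE-combined first, and a
#'   single prior — whose width is the mean of the two modality prior widths —
#'   biases the combined estimate.
#'
#' Defaults reflect the study conditions the generator emulates: Weber
#' fractions rise with background noise identically in both modalities
#' (0.13 / 0.17 / 0.22 for no / low / high noise), and the visual prior is
#' narrower (stronger central tendency) than the auditory one (177 vs 282 ms).
#'
#' @param wf Weber fractions per noise level. Either a named numeric vector
#'   `c(no=, low=, high=)` applied to both modalities, or a data frame with
#'   columns `modality` (`"V"`/`"A"`), `noise`, `wf`.
#' @param prior_width_ms Named numeric vector `c(V=, A=)` of prior standard
#'   deviations (ms).
#' @param prior_mean_ms Prior mean (ms), or `"auto"` to use the design's mean
#'   stimulus duration.
#' @param motor_noise_cv Coefficient of variation of multiplicative motor
#'   noise added to reproductions (0 disables it).
#' @param av_architecture `"model1"` or `"model2"` (default): generative
#'   integration order for audiovisual reproduction.
#' @param av_wf Optional named numeric vector of audiovisual Weber fractions
#'   keyed by condition id (e.g. `"AV.high.low"`); by default the optimal
#'   combination of the two unisensory Weber fractions is used.
#' @param seed Integer seed; identical parameters and seed give identical
#'   trial tables.
#'
#' @return An object of class `bt_observer`.
#' @examples
#' obs <- observer_params(seed = 1)
#' obs
#' @export
observer_params <- function(wf = c(no = 0.13, low = 0.17, high = 0.22),
                            prior_width_ms = c(V = 177, A = 282),
                            prior_mean_ms = "auto",
                            motor_noise_cv = 0,
                            av_architecture = c("model2", "model1"),
                            av_wf = NULL,
                            seed = 1L) {
  av_architecture <- match.arg(av_architecture)

  if (is.data.frame(wf)) {
    stopifnot(all(c("modality", "noise", "wf") %in% names(wf)))
    wf_tbl <- tibble::as_tibble(wf[, c("modality", "noise", "wf")])
  } else {
    if (is.null(names(wf)) || !all(c("no", "low", "high") %in% names(wf))) {
      abort("`wf` must be named with levels 'no', 'low', 'high' (or be a data frame).")
    }
    wf_tbl <- tidyr::expand_grid(modality = c("V", "A"), noise = c("no", "low", "high"))
    wf_tbl$wf <- unname(wf[wf_tbl$noise])
  }
  if (any(!is.finite(wf_tbl$wf)) || any(wf_tbl$wf <= 0)) {
    abort("All Weber fractions must be positive and finite.")
  }
  if (is.null(names(prior_width_ms)) || !all(c("V", "A") %in% names(prior_width_ms))) {
    abort("`prior_width_ms` must be named with entries 'V' and 'A'.")
  }
  if (any(prior_width_ms <= 0)) abort("`prior_width_ms` entries must be positive.")
  if (!identical(prior_mean_ms, "auto")) check_positive_scalar(prior_mean_ms, "prior_mean_ms")
  if (!is.numeric(motor_noise_cv) || motor_noise_cv < 0) {
    abort("`motor_noise_cv` must be nonnegative.")
  }
  if (!is.null(av_wf) && (is.null(names(av_wf)) || any(av_wf <= 0))) {
    abort("`av_wf` must be a named positive numeric vector keyed by condition id.")
  }
  seed <- as.integer(seed)
  if (is.na(seed)) abort("`seed` must be an integer.")

  structure(
    list(
      wf = wf_tbl,
      prior_width_ms = prior_width_ms[c("V", "A")],
      prior_mean_ms = prior_mean_ms,
      motor_noise_cv = motor_noise_cv,
      av_architecture = av_architecture,
      av_wf = av_wf,
      seed = seed
    ),
    class = "bt_observer"
  )
}

#' @export
print.bt_observer <- function(x, ...) {
  cat("<bt_observer>\n")
  wfs <- dplyr::mutate(x$wf, lab = paste0(.data$modality, ":", .data$noise, "=", .data$wf))
  cat("  wf:", paste(wfs$lab, collapse = " "), "\n")
  cat("  prior widths: V =", x$prior_width_ms[["V"]], "ms, A =",
      x$prior_width_ms[["A"]], "ms\n")
  cat("  prior mean:", if (identical(x$prior_mean_ms, "auto")) "auto" else
      paste(x$prior_mean_ms, "ms"), "\n")
  cat("  motor noise cv:", x$motor_noise_cv, "\n")
  cat("  AV architecture:", x$av_architecture, " seed:", x$seed, "\n")
  invisible(x)
}

# unisensory WF lookup
observer_wf_uni <- function(params, modality, noise) {
  row <- dplyr::filter(params$wf, .data$modality == !!modality, .data$noise == !!noise)
  if (nrow(row) != 1L) {
    abort(paste0("No Weber fraction defined for modality '", modality,
                 "' at noise level '", noise, "'."))
  }
  row$wf
}

# effective WF for any condition row; AV defaults to the optimal combination
observer_wf <- function(params, cond) {
  if (cond$modality == "AV") {
    if (!is.null(params$av_wf) && cond$condition %in% names(params$av_wf)) {
      return(unname(params$av_wf[[cond$condition]]))
    }
    predict_optimal_wf(
      wf_v = observer_wf_uni(params, "V", cond$vis_noise),
      wf_a = observer_wf_uni(params, "A", cond$aud_noise)
    )
  } else {
    noise <- if (cond$modality == "V") cond$vis_noise else cond$aud_noise
    observer_wf_uni(params, cond$modality, noise)
  }
}

observer_prior_mean <- function(params, design) {
  if (identical(params$prior_mean_ms, "auto")) design$mean_duration_ms else params$prior_mean_ms
}
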