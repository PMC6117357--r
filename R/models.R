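#' Gaussian belief over duration
#'
#' Likelihoods, priors, posteriors and combined audiovisual representations
#' are all carried as Gaussian densities over duration.
#'
#' @param mean_ms Center (ms).
#' @param sd_ms Positive width (ms).
#' @return An object of class `gaussian_belief`.
#' @examples
#' gaussian_belief(640, 108.8)
#' @export
gaussian_belief <- function(mean_ms, sd_ms) {
  if (!is.finite(mean_ms)) abort("`mean_ms` must be finite.")
  if (!is.finite(sd_ms) || sd_ms <= 0) abort("`sd_ms` must be positive.")
  structure(list(mean_ms = mean_ms, sd_ms = sd_ms), class = "gaussian_belief")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat(sprintf("<gaussian_belief> N(%.2f, %.2f^2) ms\n", x$mean_ms, x$sd_ms))
  invisible(x)
}

#' Reliability weights for maximum-likelihood cue combination
#'
#' Each modality's weight is its precision (inverse variance) normalized by
#' the summed precision: `w_a = sd_a^-2 / (sd_a^-2 + sd_v^-2)` and
#' symmetrically for vision.
#'
#' @param sd_a,sd_v Positive widths (ms) of the auditory and visual
#'   estimates.
#' @return A tibble with columns `w_a`, `w_v` (rows recycle over vectorized
#'   inputs); weights sum to 1.
#' @examples
#' mle_weights(100, 200)
#' @export
mle_weights <- function(sd_a, sd_v) {
  if (any(sd_a <= 0) || any(sd_v <= 0)) abort("Widths must be positive.")
  pa <- sd_a^-2
  pv <- sd_v^-2
  tibble::tibble(w_a = pa / (pa + pv), w_v = pv / (pa + pv))
}

#' Combine two Gaussian estimates by maximum-likelihood estimation
#'
#' Precision-weighted average of the two means; the combined precision is
#' the sum of the precisions, so the combined width is always below the
#' smaller input width — the statistically optimal (minimum-variance)
#' combination.
#'
#' @param a,v [gaussian_belief()] objects (auditory and visual estimates).
#' @return The combined `gaussian_belief`.
#' @examples
#' mle_combine(gaussian_belief(600, 100), gaussian_belief(700, 200))
#' @export
mle_combine <- function(a, v) {
  stopifnot(inherits(a, "gaussian_belief"), inherits(v, "gaussian_belief"))
  w <- mle_weights(a$sd_ms, v$sd_ms)
  gaussian_belief(
    mean_ms = w$w_a * a$mean_ms + w$w_v * v$mean_ms,
    sd_ms = sqrt(1 / (a$sd_ms^-2 + v$sd_ms^-2))
  )
}

#' Optimal audiovisual Weber fraction
#'
#' Because likelihood widths scale with duration (`sigma_L = WF * D`), the
#' optimal combined width implies a duration-free combined Weber fraction:
#' `WF_AV = sqrt(WF_V^2 * WF_A^2 / (WF_V^2 + WF_A^2))`, never exceeding the
#' smaller unisensory Weber fraction.
#'
#' @param wf_v,wf_a Positive unisensory Weber fractions (vectorized).
#' @return The predicted audiovisual Weber fraction(s).
#' @examples
#' predict_optimal_wf(0.17, 0.17)  # 0.17 / sqrt(2)
#' @export
predict_optimal_wf <- function(wf_v, wf_a) {
  if (any(wf_v <= 0) || any(wf_a <= 0)) abort("Weber fractions must be positive.")
  sqrt(wf_v^2 * wf_a^2 / (wf_v^2 + wf_a^2))
}

#' Likelihood width under scalar timing
#'
#' @param wf Positive Weber fraction.
#' @param duration_ms Positive duration (ms).
#' @return `wf * duration_ms` (ms); vectorized.
#' @examples
#' likelihood_width(0.17, 640)
#' @export
likelihood_width <- function(wf, duration_ms) {
  if (any(wf <= 0)) abort("`wf` must be positive.")
  if (any(duration_ms <= 0)) abort("`duration_ms` must be positive.")
  wf * duration_ms
}

#' Posterior belief from a Gaussian likelihood and prior
#'
#' The posterior mean is the likelihood mean pulled toward the prior mean by
#' `sigma_L^2 * t / (sigma_P^2 + sigma_L^2)` where `t` is the deviation of
#' the likelihood mean from the prior mean — algebraically the
#' precision-weighted average of the two means. The posterior width is
#' `sqrt(sigma_L^2 * sigma_P^2 / (sigma_L^2 + sigma_P^2))`.
#'
#' @param likelihood,prior [gaussian_belief()] objects.
#' @return The posterior `gaussian_belief`.
#' @examples
#' posterior(gaussian_belief(450, 76.5), gaussian_belief(675, 238))
#' @export
posterior <- function(likelihood, prior) {
  stopifnot(inherits(likelihood, "gaussian_belief"), inherits(prior, "gaussian_belief"))
  sl2 <- likelihood$sd_ms^2
  sp2 <- prior$sd_ms^2
  t <- likelihood$mean_ms - prior$mean_ms
  gaussian_belief(
    mean_ms = likelihood$mean_ms - sl2 * t / (sp2 + sl2),
    sd_ms = sqrt(sl2 * sp2 / (sl2 + sp2))
  )
}

#' Central-tendency slope of the Bayesian observer
#'
#' The regression slope of reproduced on stimulus duration implied by
#' Gaussian shrinkage at a single likelihood width:
#' `CT = sigma_P^2 / (sigma_P^2 + sigma_L^2)`, in (0, 1); 1 means no central
#' tendency.
#'
#' @param prior_sd,likelihood_sd Positive widths (ms); vectorized.
#' @return The dimensionless slope.
#' @examples
#' ct_slope(238, 108.8)
#' @export
ct_slope <- function(prior_sd, likelihood_sd) {
  if (any(prior_sd <= 0) || any(likelihood_sd <= 0)) abort("Widths must be positive.")
  prior_sd^2 / (prior_sd^2 + likelihood_sd^2)
}

#' Estimate the prior width from observed central tendency and sensitivity
#'
#' Inverts the slope formula at the effective likelihood width
#' `sigma_L = WF * mean_duration_ms`:
#' `sigma_P = sigma_L * sqrt(CT / (1 - CT))`. Round-trips with [ct_slope()].
#'
#' @param ct Observed central-tendency slope, strictly inside (0, 1). A slope
#'   of 1 corresponds to a flat (unbounded) prior and 0 or negative slopes
#'   are outside the model.
#' @param wf Observed Weber fraction.
#' @param mean_duration_ms Mean presented duration (ms) at which the
#'   likelihood width is evaluated.
#' @return Estimated prior width (ms); vectorized over `ct` and `wf`.
#' @examples
#' estimate_prior_width(ct_slope(238, 0.17 * 640), 0.17, 640)
#' @export
estimate_prior_width <- function(ct, wf, mean_duration_ms) {
  if (any(ct >= 1)) {
    abort("`ct` must be < 1: a slope of 1 means no central tendency and an unbounded prior width.")
  }
  if (any(ct <= 0)) abort("`ct` must be positive; nonpositive slopes are outside the shrinkage model.")
  sl <- likelihood_width(wf, mean_duration_ms)
  sl * sqrt(ct / (1 - ct))
}

#' Predicted central-tendency slope of a Bayesian reproduction observer
#'
#' Closed-form expectation of the trial-level OLS slope: the expected
#' reproduction at each duration is the posterior mean with the
#' duration-dependent likelihood width `WF * D`, and those expectations are
#' regressed on the durations. This is the exact oracle for
#' [simulate_reproduction()] at zero motor noise; evaluating the slope
#' formula once at the mean duration is only an approximation because the
#' shrinkage weight varies across levels.
#'
#' @param wf Weber fraction.
#' @param prior_sd Prior width (ms).
#' @param durations Presented durations (ms), at least 2.
#' @param prior_mean_ms Prior mean (ms); defaults to `mean(durations)`.
#' @return The expected regression slope.
#' @examples
#' d <- make_design()
#' predict_ct_slope(0.17, 238, d$reproduction_levels_ms)
#' @export
predict_ct_slope <- function(wf, prior_sd, durations,
                             prior_mean_ms = mean(durations)) {
  if (length(durations) < 2L) abort("Need at least 2 durations.")
  sl <- likelihood_width(wf, durations)
  w <- ct_slope(prior_sd, sl)
  mu <- w * durations + (1 - w) * prior_mean_ms
  unname(coef(lm(mu ~ durations))[2])
}

new_model_prediction <- function(architecture, slope, wf_av, predictions) {
  structure(
    list(
      architecture = architecture,
      predicted_av_slope = slope,
      predicted_av_wf = wf_av,
      predictions = predictions
    ),
    class = "model_prediction"
  )
}

#' Audiovisual prediction: prior integration before cue combination (model 1)
#'
#' Architecture in which each modality integrates its own prior first and
#' the resulting (already biased) unisensory posteriors are then combined by
#' maximum-likelihood estimation, with weights set by the posterior widths.
#' For every stimulus duration the combined posterior mean is computed and
#' the predicted audiovisual central-tendency slope is obtained by regressing
#' those means on the durations.
#'
#' @param wf_v,wf_a Unisensory Weber fractions.
#' @param prior_v,prior_a [gaussian_belief()] priors for each modality.
#' @param durations Stimulus durations (ms), at least 2.
#' @return A `model_prediction` with `architecture = "model1"`,
#'   `predicted_av_slope`, `predicted_av_wf` (optimal combination of the
#'   input Weber fractions) and the per-duration predicted means.
#' @examples
#' p <- gaussian_belief(675, 238)
#' predict_model1(0.17, 0.17, p, p, make_design()$reproduction_levels_ms)
#' @export
predict_model1 <- function(wf_v, wf_a, prior_v, prior_a, durations) {
  stopifnot(inherits(prior_v, "gaussian_belief"), inherits(prior_a, "gaussian_belief"))
  if (length(durations) < 2L) abort("Need at least 2 durations.")
  means <- purrr::map_dbl(durations, function(D) {
    post_v <- posterior(gaussian_belief(D, likelihood_width(wf_v, D)), prior_v)
    post_a <- posterior(gaussian_belief(D, likelihood_width(wf_a, D)), prior_a)
    mle_combine(post_a, post_v)$mean_ms
  })
  slope <- unname(coef(lm(means ~ durations))[2])
  new_model_prediction(
    "model1", slope, predict_optimal_wf(wf_v, wf_a),
    tibble::tibble(stimulus_ms = durations, predicted_mean_ms = means)
  )
}

#' Audiovisual prediction: cue combination before prior integration (model 2)
#'
#' Architecture in which the unbiased unisensory representations are first
#' combined by maximum-likelihood estimation and a single prior — centered on
#' the mean duration, with width equal to the average of the two modality
#' prior widths — then biases the combined representation. In the default
#' regression mode the posterior mean is computed per duration and the slope
#' comes from regressing those means on the durations; `mode = "effective"`
#' instead evaluates the slope formula once at the effective likelihood
#' width `WF_AV * mean(durations)`.
#'
#' @param wf_v,wf_a Unisensory Weber fractions.
#' @param prior_v_sd,prior_a_sd Unisensory prior widths (ms); the shared
#'   audiovisual prior width is their mean.
#' @param durations Stimulus durations (ms), at least 2.
#' @param prior_mean_ms Prior mean (ms); defaults to `mean(durations)`.
#' @param mode `"regression"` (default) or `"effective"`.
#' @return A `model_prediction` with `architecture = "model2"`.
#' @examples
#' predict_model2(0.17, 0.17, 238, 238, make_design()$reproduction_levels_ms)
#' @export
predict_model2 <- function(wf_v, wf_a, prior_v_sd, prior_a_sd, durations,
                           prior_mean_ms = mean(durations),
                           mode = c("regression", "effective")) {
  mode <- match.arg(mode)
  if (any(c(prior_v_sd, prior_a_sd) <= 0)) abort("Prior widths must be positive.")
  if (length(durations) < 2L) abort("Need at least 2 durations.")
  wf_av <- predict_optimal_wf(wf_v, wf_a)
  sp_av <- (prior_v_sd + prior_a_sd) / 2
  prior <- gaussian_belief(prior_mean_ms, sp_av)

  if (mode == "regression") {
    means <- purrr::map_dbl(durations, function(D) {
      posterior(gaussian_belief(D, likelihood_width(wf_av, D)), prior)$mean_ms
    })
    slope <- unname(coef(lm(means ~ durations))[2])
    preds <- tibble::tibble(stimulus_ms = durations, predicted_mean_ms = means)
  } else {
    sl <- likelihood_width(wf_av, mean(durations))
    slope <- ct_slope(sp_av, sl)
    w <- ct_slope(sp_av, likelihood_width(wf_av, durations))
    preds <- tibble::tibble(
      stimulus_ms = durations,
      predicted_mean_ms = w * durations + (1 - w) * prior_mean_ms
    )
  }
  new_model_prediction("model2", slope, wf_av, preds)
}

#' Central tendency as a function of Weber fraction, per prior width
#'
#' Evaluates the predicted slope over a Weber-fraction grid for one or more
#' prior widths, at the effective likelihood width `WF * mean_duration_ms`.
#' Wider priors give uniformly larger slopes (weaker central tendency), and
#' every curve decreases in the Weber fraction.
#'
#' @param prior_sd One or more prior widths (ms).
#' @param wf_grid Positive Weber-fraction grid.
#' @param mean_duration_ms Mean presented duration (ms).
#' @return A tibble with columns `prior_sd_ms`, `wf`, `ct_slope`.
#' @examples
#' ct_wf_curve(c(100, 300, 500), seq(0.05, 0.3, by = 0.05), 640)
#' @export
ct_wf_curve <- function(prior_sd, wf_grid, mean_duration_ms) {
  if (any(wf_grid <= 0)) abort("`wf_grid` must be positive.")
  tidyr::expand_grid(prior_sd_ms = prior_sd, wf = wf_grid) |>
    dplyr::mutate(
      ct_slope = ct_slope(.data$prior_sd_ms,
                          likelihood_width(.data$wf, mean_duration_ms))
    )
}

#' @export
print.model_prediction <- function(x, ...) {
  cat("<model_prediction> ", x$architecture, "\n", sep = "")
  cat(sprintf("  predicted AV slope = %.3f, predicted AV WF = %.3f\n",
              x$predicted_av_slope, x$predicted_av_wf))
  invisible(x)
}
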