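#' Exclude outlier reproductions
#'
#' Removes trials whose reproduced duration deviates more than `k` standard
#' deviations from the cell mean, in a single pass: means and SDs are
#' computed from the unfiltered data. By default the cell is each condition
#' crossed with each stimulus level (`by = "level"`); `by = "condition"`
#' pools levels within a condition.
#'
#' @param trials Reproduction trial tibble (may mix conditions; cells are
#'   formed by the grouping columns present).
#' @param k Deviation threshold in SD units (default 3).
#' @param by `"level"` (condition x stimulus level, default) or
#'   `"condition"`.
#' @return The filtered tibble, with attribute `n_excluded` giving the number
#'   of removed rows. Zero-variance cells exclude nothing.
#' @examples
#' d <- make_design()
#' obs <- observer_params(seed = 4)
#' tr <- simulate_reproduction(d, obs, "V.high.none")
#' nrow(tr) - nrow(exclude_outliers(tr))
#' @export
exclude_outliers <- function(trials, k = 3, by = c("level", "condition")) {
  by <- match.arg(by)
  if (k < 0) abort("`k` must be nonnegative.")
  grp <- intersect(c("subject", "modality", "vis_noise", "aud_noise",
                     if (by == "level") "stimulus_ms"), names(trials))
  out <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(
      .m = mean(.data$reproduced_ms),
      .s = sd(.data$reproduced_ms),
      .keep_row = is.na(.s) | .s == 0 |
        abs(.data$reproduced_ms - .m) <= k * .s
    ) |>
    dplyr::ungroup()
  kept <- dplyr::select(dplyr::filter(out, .data$.keep_row),
                        -dplyr::all_of(c(".m", ".s", ".keep_row")))
  attr(kept, "n_excluded") <- nrow(trials) - nrow(kept)
  kept
}

#' Quantify central tendency by linear regression
#'
#' Regresses reproduced duration on stimulus duration by ordinary least
#' squares over individual trials. The slope indexes central tendency: 1
#' means veridical reproduction, smaller values mean stronger attraction
#' toward the mean duration. Outliers beyond `k` SD of the cell mean are
#' excluded first (see [exclude_outliers()]), mirroring the standard
#' preprocessing for this task.
#'
#' @param trials Reproduction trials for a single condition.
#' @param exclude Apply the outlier rule before fitting (default `TRUE`).
#' @param k SD threshold for the outlier rule.
#' @return An object of class `central_tendency_fit` with `slope`,
#'   `intercept_ms`, `overall_bias_ms` (mean reproduced minus mean stimulus,
#'   after exclusion), `n_used`, `n_excluded`, `r2`, and the trial data.
#'   [tidy()], [glance()] and [ggplot2::autoplot()] methods are provided.
#' @examples
#' d <- make_design()
#' obs <- observer_params(seed = 5)
#' fit <- fit_central_tendency(simulate_reproduction(d, obs, "V.low.none"))
#' fit$slope
#' @export
fit_central_tendency <- function(trials, exclude = TRUE, k = 3) {
  if (nrow(trials) == 0L) abort("`trials` is empty.")
  check_single_condition(trials, c("modality", "vis_noise", "aud_noise"))
  n_in <- nrow(trials)
  used <- if (exclude) exclude_outliers(trials, k = k) else trials
  n_excluded <- n_in - nrow(used)

  if (dplyr::n_distinct(used$stimulus_ms) < 2L) {
    abort("Need at least 2 distinct stimulus levels to fit a slope.")
  }
  m <- lm(reproduced_ms ~ stimulus_ms, data = used)
  structure(
    list(
      slope = unname(coef(m)[2]),
      intercept_ms = unname(coef(m)[1]),
      overall_bias_ms = mean(used$reproduced_ms) - mean(used$stimulus_ms),
      n_used = nrow(used),
      n_excluded = as.integer(n_excluded),
      # suppressed: summary.lm warns on exact-line (zero-residual) input
      r2 = suppressWarnings(summary(m)$r.squared),
      model = m,
      data = used
    ),
    class = "central_tendency_fit"
  )
}

#' Overall reproduction bias
#'
#' Difference between the mean reproduced duration and the mean of the
#' stimulus durations as presented. If central tendency were the only source
#' of reproduction error this would be zero, because Bayesian shrinkage moves
#' individual estimates toward the mean without moving the grand mean.
#'
#' @param trials Non-empty reproduction trials.
#' @return Bias in ms (positive = overestimation).
#' @examples
#' tr <- tibble::tibble(stimulus_ms = c(450, 900), reproduced_ms = c(500, 950))
#' overall_bias(tr)
#' @export
overall_bias <- function(trials) {
  if (nrow(trials) == 0L) abort("`trials` is empty.")
  mean(trials$reproduced_ms) - mean(trials$stimulus_ms)
}

#' @export
print.central_tendency_fit <- function(x, ...) {
  cat("<central_tendency_fit>  OLS, ", x$n_used, " trials (",
      x$n_excluded, " excluded)\n", sep = "")
  cat(sprintf("  slope = %.3f, intercept = %.1f ms, overall bias = %+.1f ms, R2 = %.3f\n",
              x$slope, x$intercept_ms, x$overall_bias_ms, x$r2))
  invisible(x)
}
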