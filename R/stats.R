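#' Paired bootstrap test
#'
#' Resamples the paired units (e.g. subject-by-condition means) with
#' replacement, computes the mean difference per resample, and reports the
#' two-sided percentile p-value with a +1 continuity correction:
#' `p = 2 * min(P(diff* <= 0), P(diff* >= 0))`, capped at 1. Cohen's d is the
#' mean difference over the SD of the differences (0 when every difference
#' is 0).
#'
#' @param x,y Paired numeric vectors (at least 2 pairs).
#' @param n_boot Number of bootstrap resamples (at least 1000; default
#'   10000).
#' @param seed Optional integer seed making the resampling deterministic.
#' @return A one-row tibble: `mean_diff`, `p_value`, `effect_size_d`,
#'   `ci_lower`, `ci_upper` (95% percentile CI of the mean difference),
#'   `n_pairs`, `n_boot`.
#' @examples
#' bootstrap_paired_test(rnorm(10, 1), rnorm(10), n_boot = 1000, seed = 1)
#' @export
bootstrap_paired_test <- function(x, y, n_boot = 10000, seed = NULL) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 2L) abort("Need at least 2 pairs.")
  if (n_boot < 1000) abort("`n_boot` must be at least 1000.")
  d <- x - y
  boot <- function() {
    idx <- sample.int(n, n * n_boot, replace = TRUE)
    colMeans(matrix(d[idx], nrow = n))
  }
  bm <- if (is.null(seed)) boot() else withr_seed(seed, boot())
  p_lo <- (sum(bm <= 0) + 1) / (n_boot + 1)
  p_hi <- (sum(bm >= 0) + 1) / (n_boot + 1)
  sd_d <- sd(d)
  tibble::tibble(
    mean_diff = mean(d),
    p_value = min(1, 2 * min(p_lo, p_hi)),
    effect_size_d = if (sd_d == 0) 0 else mean(d) / sd_d,
    ci_lower = unname(stats::quantile(bm, 0.025)),
    ci_upper = unname(stats::quantile(bm, 0.975)),
    n_pairs = n,
    n_boot = as.integer(n_boot)
  )
}

#' Bonferroni adjustment for a fixed family size
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m Number of comparisons in the family (default 3).
#' @return `pmin(1, m * p)`, elementwise.
#' @examples
#' bonferroni(c(0.01, 0.5), m = 3)
#' @export
bonferroni <- function(p, m = 3) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  pmin(1, m * p)
}

#' Paired t-test with Cohen's d
#'
#' @param x,y Paired numeric vectors (at least 2 pairs).
#' @return A one-row tibble: `t`, `df`, `p_value`, `cohen_d`, `mean_diff`.
#'   Zero-variance differences give `t = 0` when the mean difference is 0 and
#'   a signed infinite `t` (with `p_value = 0`) otherwise.
#' @examples
#' paired_t(c(1, 2, 3, 4), c(0.5, 1.4, 2.2, 3.1))
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 2L) abort("Need at least 2 pairs.")
  d <- x - y
  sd_d <- sd(d)
  if (sd_d == 0) {
    md <- mean(d)
    t <- if (md == 0) 0 else sign(md) * Inf
    return(tibble::tibble(
      t = t, df = n - 1L, p_value = if (md == 0) 1 else 0,
      cohen_d = t, mean_diff = md
    ))
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble::tibble(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    cohen_d = mean(d) / sd_d,
    mean_diff = mean(d)
  )
}

#' Regress measured values on model-predicted values
#'
#' Ordinary least squares of measurement on prediction, with the Pearson
#' correlation and 95% confidence band of the fitted line. A slope of 1 with
#' intercept 0 means the model predicts the measurements without systematic
#' over- or under-estimation.
#'
#' @param predicted,measured Equal-length numeric vectors (at least 3).
#' @return An object of class `prediction_regression` with `slope`,
#'   `intercept`, `r`, `r_p_value`, `n`, the fitted `model`, the data and a
#'   `band` tibble (`predicted`, `fit`, `lwr`, `upr`). [tidy()] and
#'   [ggplot2::autoplot()] methods are provided.
#' @examples
#' pr <- regress_pred_vs_meas(c(0.1, 0.15, 0.2, 0.25), c(0.11, 0.14, 0.19, 0.27))
#' tidy(pr)
#' @export
regress_pred_vs_meas <- function(predicted, measured) {
  if (length(predicted) != length(measured)) {
    abort("`predicted` and `measured` must have equal length.")
  }
  if (length(predicted) < 3L) abort("Need at least 3 points.")
  if (sd(predicted) == 0) abort("`predicted` is constant; the correlation is undefined.")
  df <- tibble::tibble(predicted = predicted, measured = measured)
  m <- lm(measured ~ predicted, data = df)
  ct <- cor.test(predicted, measured)
  grid <- tibble::tibble(
    predicted = seq(min(predicted), max(predicted), length.out = 100)
  )
  band <- cbind(grid, predict(m, newdata = grid, interval = "confidence"))
  structure(
    list(
      slope = unname(coef(m)[2]),
      intercept = unname(coef(m)[1]),
      r = unname(ct$estimate),
      r_p_value = ct$p.value,
      n = length(predicted),
      model = m,
      data = df,
      band = tibble::as_tibble(band)
    ),
    class = "prediction_regression"
  )
}

#' @export
print.prediction_regression <- function(x, ...) {
  cat("<prediction_regression> n =", x$n, "\n")
  cat(sprintf("  measured = %.3f * predicted %+.3f,  r = %.3f (p = %.3g)\n",
              x$slope, x$intercept, x$r, x$r_p_value))
  invisible(x)
}
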