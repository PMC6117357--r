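rep_trials <- function(stimulus_ms, reproduced_ms, modality = "V") {
  tibble::tibble(
    subject = "s01", modality = modality, vis_noise = "low",
    aud_noise = "none", stimulus_ms = stimulus_ms,
    reproduced_ms = reproduced_ms
  )
}

test_that("the 3-SD rule removes exactly the planted outlier", {
  set.seed(101)
  vals <- c(rnorm(60, 600, 10), 5000)
  tr <- rep_trials(rep(600, 61), vals)
  # direct check of the rule on the unfiltered cell
  expect_true(abs(5000 - mean(vals)) > 3 * sd(vals))
  expect_true(all(abs(vals[1:60] - mean(vals)) <= 3 * sd(vals)))
  kept <- exclude_outliers(tr)
  expect_equal(nrow(kept), 60)
  expect_equal(attr(kept, "n_excluded"), 1L)
  expect_false(5000 %in% kept$reproduced_ms)
})

test_that("degenerate spreads behave as limiting cases of the rule", {
  tr <- rep_trials(rep(600, 10), rep(640, 10))
  expect_equal(nrow(exclude_outliers(tr)), 10)       # zero variance: keep all
  tr2 <- rep_trials(rep(600, 5), c(640, 640, 640, 650, 630))
  kept <- exclude_outliers(tr2, k = 0)               # k = 0: only the mean survives
  expect_equal(kept$reproduced_ms, c(640, 640, 640))
})

test_that("condition-level vs pooled outlier granularity differ when level means differ", {
  set.seed(7)
  tr <- rep_trials(rep(c(450, 900), each = 40),
                   c(rnorm(40, 460, 5), rnorm(40, 880, 5)))
  # a 930-ms reproduction of a 900-ms stimulus is ordinary at its level but
  # looks extreme against the pooled-condition spread only if SD were small;
  # here pooling inflates the SD so nothing is removed either way, but the
  # grouping is observable through the cell means used
  by_level <- exclude_outliers(tr, by = "level")
  by_cond <- exclude_outliers(tr, by = "condition")
  expect_s3_class(by_level, "tbl_df")
  expect_s3_class(by_cond, "tbl_df")
  # an outlier relative to its own level that is unremarkable pooled
  tr2 <- dplyr::bind_rows(tr, rep_trials(450, 700))
  expect_equal(attr(exclude_outliers(tr2, by = "level"), "n_excluded"), 1L)
  expect_equal(attr(exclude_outliers(tr2, by = "condition"), "n_excluded"), 0L)
})

test_that("central-tendency regression reproduces exact lines", {
  d <- make_design()
  x <- rep(d$reproduction_levels_ms, each = 3)
  fit <- fit_central_tendency(rep_trials(x, 0.8 * x + 127.3))
  expect_equal(fit$slope, 0.8, tolerance = 1e-10)
  expect_equal(fit$intercept_ms, 127.3, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)

  ident <- fit_central_tendency(rep_trials(x, x))
  expect_equal(ident$slope, 1, tolerance = 1e-10)
  expect_equal(ident$intercept_ms, 0, tolerance = 1e-8)
  expect_equal(ident$overall_bias_ms, 0, tolerance = 1e-10)
})

test_that("fewer than two stimulus levels cannot support a slope", {
  expect_error(fit_central_tendency(rep_trials(rep(640, 20), rnorm(20, 640, 5))),
               "2 distinct")
  expect_error(fit_central_tendency(rep_trials(numeric(0), numeric(0))), "empty")
})

test_that("a constant shift moves the bias but not the slope", {
  d <- make_design()
  obs <- observer_params(seed = 23)
  tr <- simulate_reproduction(d, obs, "V.low.none")
  shifted <- dplyr::mutate(tr, reproduced_ms = reproduced_ms + 50)
  f0 <- fit_central_tendency(tr, exclude = FALSE)
  f1 <- fit_central_tendency(shifted, exclude = FALSE)
  expect_equal(f1$slope, f0$slope, tolerance = 1e-10)
  expect_equal(f1$overall_bias_ms, f0$overall_bias_ms + 50, tolerance = 1e-10)
  expect_equal(overall_bias(shifted), overall_bias(tr) + 50, tolerance = 1e-10)
})

test_that("overall bias matches the closed-form expectation of pure shrinkage", {
  d <- make_design(reps_reproduction = 600)
  obs <- observer_params(motor_noise_cv = 0, seed = 29)
  tr <- simulate_reproduction(d, obs, "V.low.none")
  # at a fixed shrinkage weight the grand mean is untouched; with the
  # scalar-timing weight w(D) the exact expectation picks up a small
  # negative covariance term mean(w(D) * (D - Dbar))
  D <- d$reproduction_levels_ms
  w <- ct_slope(177, 0.17 * D)
  expected <- mean(w * D + (1 - w) * d$mean_duration_ms) - mean(D)
  mc_se <- sqrt(sum((w * 0.17 * D)^2 / 600) / 7^2)
  expect_lt(abs(overall_bias(tr) - expected), 4 * mc_se)
  expect_lt(abs(expected), 0.025 * d$mean_duration_ms)
  expect_error(overall_bias(tr[0, ]), "empty")
})

test_that("slope decreases monotonically with the generating Weber fraction", {
  d <- make_design(reps_reproduction = 500)
  slopes <- vapply(c(0.08, 0.14, 0.20, 0.28), function(w) {
    obs <- observer_params(wf = c(no = w, low = w, high = w),
                           prior_width_ms = c(V = 200, A = 200),
                           motor_noise_cv = 0, seed = 31)
    fit_central_tendency(simulate_reproduction(d, obs, "V.no.none"))$slope
  }, numeric(1))
  expect_true(all(diff(slopes) < 0))
})
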