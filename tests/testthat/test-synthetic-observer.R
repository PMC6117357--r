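test_that("identical parameters and seed give byte-identical trial tables", {
  d <- make_design()
  obs <- observer_params(seed = 42)
  expect_identical(simulate_discrimination(d, obs, "V.low.none"),
                   simulate_discrimination(d, obs, "V.low.none"))
  expect_identical(simulate_reproduction(d, obs, "AV.high.low"),
                   simulate_reproduction(d, obs, "AV.high.low"))
  obs2 <- observer_params(seed = 43)
  expect_false(identical(simulate_discrimination(d, obs, "A.none.no"),
                         simulate_discrimination(d, obs2, "A.none.no")))
})

test_that("unknown conditions are rejected with the list of known ones", {
  d <- make_design()
  obs <- observer_params(seed = 1)
  expect_error(simulate_discrimination(d, obs, "AV.low.low"), "AV.high.high")
  expect_error(simulate_reproduction(d, obs, "X"), "Known conditions")
})

test_that("discrimination responses follow the generating psychometric function", {
  # at the standard the judged-longer probability is 1/2; at 900 ms with
  # WF 0.17 it is pnorm(260 / 108.8) = 0.9917 (normal-CDF oracle)
  d <- make_design(comparison_levels_ms = c(640, 900), n_levels = 2,
                   reps_discrimination = 10000)
  obs <- observer_params(wf = c(no = 0.17, low = 0.17, high = 0.17), seed = 7)
  tr <- simulate_discrimination(d, obs, "V.no.none")
  agg <- aggregate_binary_responses(tr)
  p_oracle <- pnorm((c(640, 900) - 640) / (0.17 * 640))
  se <- sqrt(p_oracle * (1 - p_oracle) / 10000)
  expect_lt(abs(agg$k[1] / agg$n[1] - 0.5), 4 * se[1])
  expect_lt(abs(agg$k[2] / agg$n[2] - p_oracle[2]), 4 * se[2] + 1e-4)
})

test_that("estimate mode produces monotone psychometric data at matched noise", {
  d <- make_design(reps_discrimination = 2000)
  obs <- observer_params(seed = 11)
  tr <- simulate_discrimination(d, obs, "A.none.low", mode = "estimate")
  agg <- aggregate_binary_responses(tr)
  p <- agg$k / agg$n
  expect_true(all(diff(p) > 0))
  # per-interval width WF*D/sqrt(2) keeps the effective decision noise near
  # the psychometric-mode value, so the fitted WF should land near 0.17
  fit <- fit_cumulative_normal(tr)
  expect_lt(abs(fit$weber_fraction - 0.17), 0.03)
})

test_that("reproduction approaches veridical as sensory noise vanishes", {
  d <- make_design(reps_reproduction = 50)
  obs <- observer_params(wf = c(no = 1e-4, low = 1e-4, high = 1e-4),
                         motor_noise_cv = 0, seed = 3)
  tr <- simulate_reproduction(d, obs, "V.no.none")
  expect_lt(max(abs(tr$reproduced_ms - tr$stimulus_ms)), 1)
  expect_gt(fit_central_tendency(tr)$slope, 0.999)
})

test_that("generated reproduction slope matches the closed-form Bayesian prediction", {
  d <- make_design(reps_reproduction = 600)
  obs <- observer_params(wf = c(no = 0.17, low = 0.17, high = 0.17),
                         prior_width_ms = c(V = 238, A = 238),
                         motor_noise_cv = 0, seed = 21)
  tr <- simulate_reproduction(d, obs, "V.low.none")
  fit <- fit_central_tendency(tr, exclude = FALSE)
  pred <- predict_ct_slope(0.17, 238, d$reproduction_levels_ms,
                           prior_mean_ms = d$mean_duration_ms)
  se <- summary(fit$model)$coefficients["stimulus_ms", "Std. Error"]
  expect_lt(abs(fit$slope - pred), 3 * se)
})

test_that("per-level reproduction means converge to the shrinkage formula", {
  d <- make_design(reps_reproduction = 2000)
  obs <- observer_params(wf = c(no = 0.2, low = 0.2, high = 0.2),
                         prior_width_ms = c(V = 200, A = 200),
                         motor_noise_cv = 0, seed = 5)
  tr <- simulate_reproduction(d, obs, "A.none.no")
  by_level <- tr |>
    dplyr::group_by(stimulus_ms) |>
    dplyr::summarise(m = mean(reproduced_ms), .groups = "drop")
  w <- ct_slope(200, 0.2 * by_level$stimulus_ms)
  expected <- w * by_level$stimulus_ms + (1 - w) * d$mean_duration_ms
  mc_se <- (w * 0.2 * by_level$stimulus_ms) / sqrt(2000)
  expect_true(all(abs(by_level$m - expected) < 4 * mc_se))
})

test_that("audiovisual integration weakens central tendency relative to unisensory", {
  # equal Weber fractions and prior widths: combining the two cues shrinks
  # the likelihood width, so the AV slope must exceed the unisensory slope
  d <- make_design(reps_reproduction = 400)
  obs <- observer_params(wf = c(no = 0.2, low = 0.2, high = 0.2),
                         prior_width_ms = c(V = 200, A = 200),
                         av_architecture = "model2", motor_noise_cv = 0,
                         seed = 13)
  s_av <- fit_central_tendency(simulate_reproduction(d, obs, "AV.high.high"))$slope
  s_v <- fit_central_tendency(simulate_reproduction(d, obs, "V.high.none"))$slope
  expect_gt(s_av, s_v)
})

test_that("model2 generates a weaker AV central tendency than model1", {
  d <- make_design(reps_reproduction = 400)
  base <- list(wf = c(no = 0.2, low = 0.2, high = 0.2),
               prior_width_ms = c(V = 220, A = 220), motor_noise_cv = 0)
  s1 <- fit_central_tendency(simulate_reproduction(
    d, do.call(observer_params,
               c(base, list(av_architecture = "model1", seed = 17))),
    "AV.high.high"))$slope
  s2 <- fit_central_tendency(simulate_reproduction(
    d, do.call(observer_params,
               c(base, list(av_architecture = "model2", seed = 17))),
    "AV.high.high"))$slope
  expect_gt(s2, s1)
})

test_that("reproductions stay positive even under extreme motor noise", {
  d <- make_design(reps_reproduction = 300)
  obs <- observer_params(motor_noise_cv = 1, seed = 19)
  tr <- simulate_reproduction(d, obs, "V.high.none")
  expect_true(all(tr$reproduced_ms > 0))
})

test_that("observer parameter validation rejects out-of-range values", {
  expect_error(observer_params(wf = c(no = -0.1, low = 0.17, high = 0.22)),
               "positive")
  expect_error(observer_params(prior_width_ms = c(V = 0, A = 282)), "positive")
  expect_error(observer_params(motor_noise_cv = -1), "nonnegative")
  expect_error(observer_params(wf = c(a = 1, b = 2)), "named")
})
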