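test_that("reliability weights follow inverse-variance weighting", {
  expect_equal(mle_weights(100, 100), tibble::tibble(w_a = 0.5, w_v = 0.5))
  w <- mle_weights(100, 200)
  expect_equal(w$w_a, 0.8)
  expect_equal(w$w_v, 0.2)
  expect_gt(mle_weights(100, 1e9)$w_a, 1 - 1e-10)
  expect_equal(mle_weights(c(100, 50), c(200, 50))$w_a +
               mle_weights(c(100, 50), c(200, 50))$w_v, c(1, 1))
  expect_error(mle_weights(-1, 100), "positive")
})

test_that("MLE combination matches the closed form and the density-product oracle", {
  comb <- mle_combine(gaussian_belief(600, 100), gaussian_belief(700, 200))
  expect_equal(comb$mean_ms, 620)
  expect_equal(comb$sd_ms, sqrt(8000), tolerance = 1e-10)

  same <- mle_combine(gaussian_belief(640, 80), gaussian_belief(640, 80))
  expect_equal(same$mean_ms, 640)
  expect_equal(same$sd_ms, 80 / sqrt(2), tolerance = 1e-12)

  set.seed(5)
  for (i in 1:20) {
    m <- runif(2, 300, 900); s <- runif(2, 30, 300)
    got <- mle_combine(gaussian_belief(m[1], s[1]), gaussian_belief(m[2], s[2]))
    want <- grid_product_oracle(m[1], s[1], m[2], s[2])
    expect_lt(rel_err(got$mean_ms, want$mean), 1e-6)
    expect_lt(rel_err(got$sd_ms, want$sd), 1e-6)
    expect_lt(got$sd_ms, min(s))
  }
})

test_that("optimal audiovisual Weber fraction matches the quadratic combination", {
  expect_equal(predict_optimal_wf(0.17, 0.17), 0.17 / sqrt(2), tolerance = 1e-12)
  expect_equal(predict_optimal_wf(0.2, 1e6), 0.2, tolerance = 1e-6)
  grid <- tidyr::expand_grid(v = seq(0.05, 0.5, length.out = 10),
                             a = seq(0.05, 0.5, length.out = 10))
  expect_true(all(predict_optimal_wf(grid$v, grid$a) <= pmin(grid$v, grid$a)))
  expect_error(predict_optimal_wf(0, 0.1), "positive")
})

test_that("Weber-fraction combination is the duration-free shadow of MLE combination", {
  # at any duration the combined width implied by MLE combination divided by
  # the duration equals the combined Weber fraction (scale invariance)
  for (D in c(120, 640, 1500)) {
    s_av <- mle_combine(gaussian_belief(D, 0.23 * D),
                        gaussian_belief(D, 0.11 * D))$sd_ms
    expect_equal(s_av / D, predict_optimal_wf(0.11, 0.23), tolerance = 1e-12)
  }
})

test_that("likelihood width scales linearly with duration", {
  expect_equal(likelihood_width(0.17, 640), 108.8)
  expect_equal(likelihood_width(0.17, 1280), 2 * 108.8)
  expect_error(likelihood_width(-0.1, 640), "positive")
  expect_error(likelihood_width(0.17, 0), "positive")
})

test_that("posterior mean and width match the deviation form and the oracle", {
  pri <- gaussian_belief(675, 238)
  expect_equal(posterior(gaussian_belief(675, 76.5), pri)$mean_ms, 675)

  post <- posterior(gaussian_belief(450, 76.5), pri)
  expect_equal(post$mean_ms, 471.1, tolerance = 0.01)
  want <- grid_product_oracle(450, 76.5, 675, 238)
  expect_lt(rel_err(post$mean_ms, want$mean), 1e-6)
  expect_lt(rel_err(post$sd_ms, want$sd), 1e-6)

  flat <- posterior(gaussian_belief(450, 76.5), gaussian_belief(675, 1e8))
  expect_equal(flat$mean_ms, 450, tolerance = 1e-6)
})

test_that("the central-tendency slope formula behaves and inverts correctly", {
  expect_equal(ct_slope(100, 100), 0.5)
  expect_equal(ct_slope(238, 108.8), 238^2 / (238^2 + 108.8^2))
  expect_equal(ct_slope(238, 108.8), 0.827, tolerance = 1e-3)
  sl <- seq(50, 400, by = 25)
  expect_true(all(diff(ct_slope(238, sl)) < 0))

  # round trip to machine precision
  for (sp in c(100, 177, 238, 282, 500)) {
    ct <- ct_slope(sp, 0.17 * 653.5)
    expect_equal(estimate_prior_width(ct, 0.17, 653.5), sp, tolerance = 1e-12)
  }
  expect_equal(estimate_prior_width(0.5, 0.17, 640), 108.8, tolerance = 1e-12)
  expect_equal(estimate_prior_width(0.827, 0.17, 640), 238, tolerance = 0.5)
  expect_error(estimate_prior_width(1, 0.17, 640), "central tendency")
  expect_error(estimate_prior_width(0, 0.17, 640), "positive")
})

test_that("model 1 reduces to the unisensory prediction for matched modalities", {
  d <- make_design()
  durs <- d$reproduction_levels_ms
  pri <- gaussian_belief(d$mean_duration_ms, 238)
  m1 <- predict_model1(0.17, 0.17, pri, pri, durs)
  expect_equal(m1$predicted_av_slope,
               predict_ct_slope(0.17, 238, durs, d$mean_duration_ms),
               tolerance = 1e-10)
  expect_equal(m1$predicted_av_wf, predict_optimal_wf(0.17, 0.17))

  # flat priors: nothing to integrate, slope -> 1
  flat <- gaussian_belief(d$mean_duration_ms, 1e7)
  expect_equal(predict_model1(0.17, 0.22, flat, flat, durs)$predicted_av_slope,
               1, tolerance = 1e-5)
})

test_that("model 1 never exceeds the larger unisensory slope", {
  d <- make_design()
  durs <- d$reproduction_levels_ms
  mu <- d$mean_duration_ms
  set.seed(9)
  for (i in 1:30) {
    wfv <- runif(1, 0.05, 0.4); wfa <- runif(1, 0.05, 0.4)
    spv <- runif(1, 80, 500); spa <- runif(1, 80, 500)
    m1 <- predict_model1(wfv, wfa, gaussian_belief(mu, spv),
                         gaussian_belief(mu, spa), durs)
    uni <- c(predict_ct_slope(wfv, spv, durs, mu),
             predict_ct_slope(wfa, spa, durs, mu))
    expect_lte(m1$predicted_av_slope, max(uni) + 1e-4)
  }
})

test_that("model 2 matches the single-width evaluation at the mean duration", {
  # durations averaging 640 ms, equal inputs: slope = sigma_P^2 /
  # (sigma_P^2 + (108.8/sqrt(2))^2) = 0.905, against model 1's 0.827
  durs <- c(540, 640, 740)
  m2 <- predict_model2(0.17, 0.17, 238, 238, durs, mode = "effective")
  expect_equal(m2$predicted_av_slope, ct_slope(238, 108.8 / sqrt(2)),
               tolerance = 1e-12)
  expect_equal(m2$predicted_av_slope, 0.905, tolerance = 1e-3)
  expect_gt(m2$predicted_av_slope, ct_slope(238, 108.8))

  # near-perfect auditory evidence: slope -> 1
  expect_equal(predict_model2(0.17, 1e-5, 238, 238,
                              c(450, 900))$predicted_av_slope,
               1, tolerance = 1e-4)
})

test_that("model 2 predicts a weaker central tendency than model 1 throughout", {
  d <- make_design()
  durs <- d$reproduction_levels_ms
  mu <- d$mean_duration_ms
  grid <- tidyr::expand_grid(wfv = seq(0.05, 0.45, length.out = 6),
                             wfa = seq(0.05, 0.45, length.out = 6),
                             sp = c(100, 200, 300, 400, 500))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    pri <- gaussian_belief(mu, g$sp)
    s1 <- predict_model1(g$wfv, g$wfa, pri, pri, durs)$predicted_av_slope
    s2 <- predict_model2(g$wfv, g$wfa, g$sp, g$sp, durs,
                         prior_mean_ms = mu)$predicted_av_slope
    expect_gte(s2, s1 - 1e-12)
  }
})

test_that("slope-vs-WF curves are ordered by prior width and decrease in WF", {
  curves <- ct_wf_curve(c(100, 200, 300, 400, 500),
                        seq(0.05, 0.35, by = 0.025), 640)
  by_prior <- split(curves, curves$prior_sd_ms)
  for (cu in by_prior) expect_true(all(diff(cu$ct_slope) < 0))
  wide <- by_prior[["500"]]$ct_slope
  narrow <- by_prior[["100"]]$ct_slope
  expect_true(all(wide > narrow))

  # the three printed prior widths at matched sensitivity order as expected
  at17 <- ct_wf_curve(c(177, 282, 238), 0.17, 640)
  slopes <- setNames(at17$ct_slope, at17$prior_sd_ms)
  expect_true(slopes[["177"]] < slopes[["238"]])
  expect_true(slopes[["238"]] < slopes[["282"]])
})

test_that("gaussian beliefs validate their width", {
  expect_error(gaussian_belief(600, 0), "positive")
  expect_error(gaussian_belief(Inf, 10), "finite")
})
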