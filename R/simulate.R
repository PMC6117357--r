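#' Simulate duration-discrimination trials
#'
#' Generates one row per two-interval forced-choice trial for a single
#' condition. In the default psychometric mode the probability of judging the
#' comparison longer than the standard is
#' `pnorm((D_comp - D_std) / (WF * D_std))`, so a cumulative-normal fit to the
#' generated data recovers the generating Weber fraction by construction. In
#' estimate mode the observer instead draws a noisy estimate of each interval
#' (per-interval width `WF * D / sqrt(2)`, so the decision noise at the
#' standard matches the psychometric mode) and compares them.
#'
#' @param design A [make_design()] object.
#' @param params An [observer_params()] object.
#' @param condition A condition id from `design$conditions$condition`.
#' @param mode `"psychometric"` (default) or `"estimate"`.
#' @param subject Subject label stored in the table.
#' @param subject_index Integer used, with the observer seed and the
#'   condition, to derive the random stream; distinct subjects get distinct
#'   streams from one observer seed.
#'
#' @return A tibble with columns `subject`, `modality`, `vis_noise`,
#'   `aud_noise`, `standard_ms`, `comparison_ms`,
#'   `resp_comparison_longer` (0/1).
#' @examples
#' d <- make_design()
#' obs <- observer_params(seed = 7)
#' trials <- simulate_discrimination(d, obs, "V.low.none")
#' head(trials)
#' @export
simulate_discrimination <- function(design, params, condition,
                                    mode = c("psychometric", "estimate"),
                                    subject = "s01", subject_index = 1L) {
  mode <- match.arg(mode)
  cond <- lookup_condition(design, condition)
  wf <- observer_wf(params, cond)
  i <- match(condition, design$conditions$condition)

  trials <- tidyr::expand_grid(
    comparison_ms = design$comparison_levels_ms,
    rep = seq_len(design$reps_discrimination)
  )
  n <- nrow(trials)
  std <- design$standard_ms

  withr_seed(derive_seed(params$seed, task = 1L, cond_index = i,
                         subject_index = subject_index), {
    resp <- if (mode == "psychometric") {
      p <- pnorm((trials$comparison_ms - std) / (wf * std))
      rbinom(n, 1L, p)
    } else {
      e_std <- rnorm(n, std, wf * std / sqrt(2))
      e_cmp <- rnorm(n, trials$comparison_ms, wf * trials$comparison_ms / sqrt(2))
      as.integer(e_cmp > e_std)
    }
    tibble::tibble(
      subject = subject,
      modality = cond$modality,
      vis_noise = cond$vis_noise,
      aud_noise = cond$aud_noise,
      standard_ms = std,
      comparison_ms = trials$comparison_ms,
      resp_comparison_longer = as.integer(resp)
    )
  })
}

#' Simulate duration-reproduction trials
#'
#' For each trial at stimulus duration `D` the observer draws a sensory
#' measurement `m ~ Normal(D, (WF*D)^2)`, shrinks it toward the prior mean by
#' the Bayesian weight `w = sigma_P^2 / (sigma_P^2 + sigma_L^2)` (with
#' `sigma_L = WF*D`), and reproduces the posterior mean
#' `w*m + (1-w)*mu_P`, optionally perturbed by multiplicative motor noise.
#' Audiovisual trials follow the observer's `av_architecture`: under
#' `"model1"` each modality's measurement is biased by its own prior and the
#' two posterior estimates are then combined with weights set by the posterior
#' widths; under `"model2"` the two measurements are combined first
#' (reliability weights from the likelihood widths) and a single prior of
#' width `(sigma_P_V + sigma_P_A)/2` biases the combined estimate.
#' Non-positive reproductions are redrawn; at realistic parameters this is
#' vanishingly rare.
#'
#' @inheritParams simulate_discrimination
#' @return A tibble with columns `subject`, `modality`, `vis_noise`,
#'   `aud_noise`, `stimulus_ms`, `reproduced_ms`.
#' @examples
#' d <- make_design()
#' obs <- observer_params(seed = 7)
#' rep_trials <- simulate_reproduction(d, obs, "A.none.high")
#' head(rep_trials)
#' @export
simulate_reproduction <- function(design, params, condition,
                                  subject = "s01", subject_index = 1L) {
  cond <- lookup_condition(design, condition)
  i <- match(condition, design$conditions$condition)
  mu_p <- observer_prior_mean(params, design)

  D <- rep(design$reproduction_levels_ms, each = design$reps_reproduction)
  n <- length(D)

  gen <- function(D) {
    n <- length(D)
    est <- if (cond$modality == "AV") {
      wf_v <- observer_wf_uni(params, "V", cond$vis_noise)
      wf_a <- observer_wf_uni(params, "A", cond$aud_noise)
      sl_v <- wf_v * D
      sl_a <- wf_a * D
      m_v <- rnorm(n, D, sl_v)
      m_a <- rnorm(n, D, sl_a)
      if (params$av_architecture == "model1") {
        sp_v <- params$prior_width_ms[["V"]]
        sp_a <- params$prior_width_ms[["A"]]
        w_v <- sp_v^2 / (sp_v^2 + sl_v^2)
        w_a <- sp_a^2 / (sp_a^2 + sl_a^2)
        post_v <- w_v * m_v + (1 - w_v) * mu_p
        post_a <- w_a * m_a + (1 - w_a) * mu_p
        # MLE combination of the two posterior estimates
        tau_v <- (sl_v^2 * sp_v^2 / (sl_v^2 + sp_v^2))^-1
        tau_a <- (sl_a^2 * sp_a^2 / (sl_a^2 + sp_a^2))^-1
        (tau_a * post_a + tau_v * post_v) / (tau_a + tau_v)
      } else {
        w_comb_a <- sl_a^-2 / (sl_a^-2 + sl_v^-2)
        m_av <- w_comb_a * m_a + (1 - w_comb_a) * m_v
        sl_av <- sqrt(sl_a^2 * sl_v^2 / (sl_a^2 + sl_v^2))
        sp_av <- mean(params$prior_width_ms)
        w <- sp_av^2 / (sp_av^2 + sl_av^2)
        w * m_av + (1 - w) * mu_p
      }
    } else {
      wf <- observer_wf(params, cond)
      sp <- params$prior_width_ms[[cond$modality]]
      sl <- wf * D
      m <- rnorm(n, D, sl)
      w <- sp^2 / (sp^2 + sl^2)
      w * m + (1 - w) * mu_p
    }
    if (params$motor_noise_cv > 0) {
      rnorm(n, est, params$motor_noise_cv * abs(est))
    } else {
      est
    }
  }

  withr_seed(derive_seed(params$seed, task = 2L, cond_index = i,
                         subject_index = subject_index), {
    reproduced <- gen(D)
    # truncate at zero by redrawing the whole trial
    bad <- which(reproduced <= 0)
    while (length(bad) > 0L) {
      reproduced[bad] <- gen(D[bad])
      bad <- bad[reproduced[bad] <= 0]
    }

    tibble::tibble(
      subject = subject,
      modality = cond$modality,
      vis_noise = cond$vis_noise,
      aud_noise = cond$aud_noise,
      stimulus_ms = D,
      reproduced_ms = reproduced
    )
  })
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
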