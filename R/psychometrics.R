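#' Aggregate binary discrimination responses by comparison level
#'
#' @param trials Discrimination trial tibble (one condition, one standard) as
#'   produced by [simulate_discrimination()] or read from the documented CSV
#'   dialect.
#' @return A tibble with one row per comparison level: `comparison_ms`, `n`
#'   (trials), `k` (judged "comparison longer").
#' @examples
#' d <- make_design()
#' obs <- observer_params(seed = 2)
#' aggregate_binary_responses(simulate_discrimination(d, obs, "V.no.none"))
#' @export
aggregate_binary_responses <- function(trials) {
  if (nrow(trials) == 0L) abort("`trials` is empty.")
  check_single_condition(trials, c("modality", "vis_noise", "aud_noise", "standard_ms"))
  trials |>
    dplyr::group_by(comparison_ms = .data$comparison_ms) |>
    dplyr::summarise(
      n = dplyr::n(),
      k = sum(.data$resp_comparison_longer),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$comparison_ms)
}

check_single_condition <- function(trials, cols) {
  cols <- intersect(cols, names(trials))
  if (nrow(dplyr::distinct(trials[, cols])) > 1L) {
    abort(paste0(
      "`trials` mixes conditions; expected a single combination of ",
      paste(cols, collapse = ", "), ". Group or filter first."
    ))
  }
  invisible(trials)
}

#' Fit a cumulative-normal psychometric function
#'
#' Maximizes the Bernoulli likelihood of "comparison longer" responses under
#' `p(D_c) = lapse/2 + (1 - lapse) * pnorm((D_c - pse) / sigma)`. The point of
#' subjective equality (PSE) is free by default; `sigma` is the just
#' noticeable difference and, divided by the standard duration, gives the
#' Weber fraction. Optimization runs Nelder-Mead over `(pse, log sigma)` from
#' a moment-based start (PSE from the 50% crossing, `sigma` from the 25–75%
#' span) plus jittered restarts; if the optimizer stalls the best estimate so
#' far is returned with `converged = FALSE` rather than an error.
#'
#' @param trials Discrimination trials for one condition, or an aggregated
#'   table from [aggregate_binary_responses()] (columns `comparison_ms`, `n`,
#'   `k`).
#' @param lapse Fixed lapse rate in `[0, 0.5)`; 0 (default) fits the pure
#'   cumulative normal.
#' @param pse_fixed Optional fixed PSE (ms); when supplied only `sigma` is
#'   fitted.
#' @param standard_ms Standard duration used for the Weber fraction; taken
#'   from the `standard_ms` column when present.
#' @return An object of class `psychometric_fit` with fields `pse_ms`,
#'   `sigma_ms`, `weber_fraction`, `standard_ms`, `n_trials`, `loglik`,
#'   `converged`, and the aggregated data. [tidy()], [glance()] and
#'   [ggplot2::autoplot()] methods are provided.
#' @examples
#' d <- make_design()
#' obs <- observer_params(seed = 3)
#' fit <- fit_cumulative_normal(simulate_discrimination(d, obs, "A.none.low"))
#' glance(fit)
#' @export
fit_cumulative_normal <- function(trials, lapse = 0, pse_fixed = NULL,
                                  standard_ms = NULL) {
  if (lapse < 0 || lapse >= 0.5) abort("`lapse` must lie in [0, 0.5).")
  if (all(c("n", "k") %in% names(trials))) {
    agg <- tibble::as_tibble(trials[, intersect(c("comparison_ms", "n", "k"),
                                                names(trials))])
  } else {
    agg <- aggregate_binary_responses(trials)
  }
  if (is.null(standard_ms)) {
    standard_ms <- if ("standard_ms" %in% names(trials)) {
      trials$standard_ms[[1]]
    } else {
      abort("Supply `standard_ms` when `trials` has no standard_ms column.")
    }
  }
  check_positive_scalar(standard_ms, "standard_ms")
  if (nrow(agg) < 2L) abort("Need at least 2 distinct comparison levels.")
  ktot <- sum(agg$k); ntot <- sum(agg$n)
  if (ktot == 0L || ktot == ntot) {
    abort(paste0(
      "Degenerate data: every response is ",
      if (ktot == 0L) "'shorter'" else "'longer'",
      "; sigma is unidentifiable."
    ))
  }

  x <- agg$comparison_ms
  nll <- function(pse, sigma) {
    p <- lapse / 2 + (1 - lapse) * pnorm((x - pse) / sigma)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(agg$k * log(p) + (agg$n - agg$k) * log1p(-p))
  }

  # moment-based start: interpolate the 50% crossing and the 25-75% span
  phat <- (agg$k + 0.5) / (agg$n + 1)
  cross <- function(level) {
    if (all(phat <= level)) return(max(x))
    if (all(phat >= level)) return(min(x))
    stats::approx(phat, x, xout = level, ties = mean)$y
  }
  pse0 <- cross(0.5)
  sig0 <- max((cross(0.75) - cross(0.25)) / (2 * qnorm(0.75)), diff(range(x)) / 20)

  starts <- list(c(pse0, log(sig0)),
                 c(pse0, log(sig0 * 3)),
                 c(mean(range(x)), log(diff(range(x)) / 2)))
  best <- NULL
  for (s in starts) {
    fit <- if (is.null(pse_fixed)) {
      optim(s, function(par) nll(par[1], exp(par[2])), method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-10))
    } else {
      o <- optim(s[2], function(par) nll(pse_fixed, exp(par)),
                 method = "Brent", lower = log(1e-3), upper = log(1e5))
      o$par <- c(pse_fixed, o$par)
      o
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }

  structure(
    list(
      pse_ms = best$par[1],
      sigma_ms = exp(best$par[2]),
      weber_fraction = exp(best$par[2]) / standard_ms,
      standard_ms = standard_ms,
      lapse = lapse,
      n_trials = as.integer(ntot),
      loglik = -best$value,
      converged = best$convergence == 0,
      data = agg
    ),
    class = "psychometric_fit"
  )
}

#' Weber fraction of a psychometric fit
#'
#' The timing-sensitivity index: the fitted cumulative-normal standard
#' deviation divided by the standard duration.
#'
#' @param fit A [fit_cumulative_normal()] object.
#' @param standard_ms Standard duration (ms); defaults to the one stored in
#'   the fit.
#' @return The dimensionless Weber fraction.
#' @examples
#' weber_fraction(
#'   structure(list(sigma_ms = 108.8, standard_ms = 640),
#'             class = "psychometric_fit")
#' )
#' @export
weber_fraction <- function(fit, standard_ms = fit$standard_ms) {
  check_positive_scalar(standard_ms, "standard_ms")
  fit$sigma_ms / standard_ms
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("<psychometric_fit>  cumulative normal, ", x$n_trials, " trials\n", sep = "")
  cat(sprintf("  PSE = %.1f ms, sigma = %.1f ms, Weber fraction = %.3f\n",
              x$pse_ms, x$sigma_ms, x$weber_fraction))
  cat(sprintf("  logLik = %.2f, converged: %s\n", x$loglik, x$converged))
  invisible(x)
}
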