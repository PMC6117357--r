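#' Configuration for a simulated-cohort experiment
#'
#' Bundles everything a full run needs: the task design, the population-level
#' observer parameters, the cohort size, per-subject parameter jitter, and
#' seeds. A persisted config ([save_run_config()] / [load_run_config()])
#' reproduces a run bit for bit.
#'
#' Per-subject heterogeneity is modeled log-normally: each subject's Weber
#' fractions and prior widths are the population values times
#' `exp(Normal(0, sdlog))` draws, so parameters stay positive and the spread
#' is a constant coefficient of variation.
#'
#' @param n_subjects Number of simulated subjects (default 7).
#' @param seed Master integer seed for the run.
#' @param design Named list of [make_design()] overrides.
#' @param observer Named list of [observer_params()] overrides (the `seed`
#'   element is managed by the run).
#' @param subject_sdlog_wf Log-normal sdlog of between-subject Weber-fraction
#'   variation (default 0.10).
#' @param subject_sdlog_prior Log-normal sdlog of between-subject prior-width
#'   variation (default 0.15).
#' @param n_boot Bootstrap resamples for the condition contrasts (default
#'   2000).
#' @return An object of class `bt_config`.
#' @examples
#' cfg <- run_config(n_subjects = 2, seed = 11)
#' cfg
#' @export
run_config <- function(n_subjects = 7, seed = 1L, design = list(),
                       observer = list(), subject_sdlog_wf = 0.10,
                       subject_sdlog_prior = 0.15, n_boot = 2000) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    abort("`n_subjects` must be a positive integer.")
  }
  if (subject_sdlog_wf < 0) abort("`subject_sdlog_wf` must be nonnegative.")
  if (subject_sdlog_prior < 0) abort("`subject_sdlog_prior` must be nonnegative.")
  if (n_boot < 1000) abort("`n_boot` must be at least 1000.")
  design <- lapply(design, function(x) if (is.list(x)) unlist(x) else x)
  observer <- lapply(observer, function(x) {
    if (is.list(x)) unlist(x) else x
  })
  bad <- setdiff(names(design), names(formals(make_design)))
  if (length(bad) > 0) {
    abort(paste0("Unknown design field(s): ", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(names(observer), setdiff(names(formals(observer_params)), "seed"))
  if (length(bad) > 0) {
    abort(paste0("Unknown observer field(s): ", paste(bad, collapse = ", ")))
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      seed = as.integer(seed),
      design = design,
      observer = observer,
      subject_sdlog_wf = as.numeric(subject_sdlog_wf),
      subject_sdlog_prior = as.numeric(subject_sdlog_prior),
      n_boot = as.integer(n_boot)
    ),
    class = "bt_config"
  )
}

#' @export
print.bt_config <- function(x, ...) {
  cat("<bt_config>", x$n_subjects, "subjects, seed", x$seed, "\n")
  invisible(x)
}

#' @rdname run_config
#' @param config A `bt_config`.
#' @param path File path for the YAML serialization.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "bt_config"))
  # named atomic vectors must go out as maps or their names are lost
  as_map <- function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  }
  out <- unclass(config)
  out$design <- lapply(out$design, as_map)
  out$observer <- lapply(out$observer, as_map)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

# subject-level observer parameters with log-normal jitter, drawn under the
# run seed so the cohort is reproducible
draw_cohort <- function(config) {
  base <- do.call(observer_params, c(config$observer, list(seed = config$seed)))
  withr_seed(derive_seed(config$seed, task = 3L, cond_index = 0L), {
    purrr::map(seq_len(config$n_subjects), function(s) {
      wf_tbl <- base$wf
      wf_tbl$wf <- wf_tbl$wf *
        exp(rnorm(nrow(wf_tbl), 0, config$subject_sdlog_wf))
      pw <- base$prior_width_ms *
        exp(rnorm(2, 0, config$subject_sdlog_prior))
      obs <- base
      obs$wf <- wf_tbl
      obs$prior_width_ms <- pw
      obs$seed <- derive_seed(config$seed, task = 4L, cond_index = 0L,
                              subject_index = s)
      obs
    })
  })
}

#' Run a full simulated experiment
#'
#' Simulates a cohort of Bayesian observers through both timing tasks in all
#' nine conditions, fits psychometric functions and central-tendency
#' regressions per subject and condition, estimates prior widths, predicts
#' the audiovisual central tendency under both integration architectures,
#' runs the condition contrasts and model-comparison statistics, and writes
#' everything (trial CSVs, fit CSVs, prediction CSVs, `stats.json`,
#' `config.yaml`, `report.md`) into `dir`.
#'
#' @param config A [run_config()] object.
#' @param dir Output directory (created if absent).
#' @param quiet Suppress progress messages.
#' @return The run directory path, invisibly.
#' @examples
#' \donttest{
#' dir <- run_experiment(run_config(n_subjects = 2, seed = 5), tempfile())
#' }
#' @export
run_experiment <- function(config, dir = tempfile("bayestime_run_"),
                           quiet = FALSE) {
  stopifnot(inherits(config, "bt_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(file.path(dir, "trials"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "fits"), showWarnings = FALSE)
  dir.create(file.path(dir, "models"), showWarnings = FALSE)
  if (!dir.exists(dir)) abort(paste0("Cannot create output directory: ", dir))

  design <- do.call(make_design, config$design)
  cohort <- draw_cohort(config)
  subjects <- sprintf("s%02d", seq_len(config$n_subjects))
  say("bayestime: run seed ", config$seed, ", ", config$n_subjects,
      " subjects, ", nrow(design$conditions), " conditions")

  # --- simulate and fit per subject x condition -------------------------
  cells <- tidyr::expand_grid(
    s = seq_len(config$n_subjects),
    ci = seq_len(nrow(design$conditions))
  )
  fits <- purrr::pmap(cells, function(s, ci) {
    cond <- design$conditions$condition[ci]
    obs <- cohort[[s]]
    disc <- simulate_discrimination(design, obs, cond,
                                    subject = subjects[s], subject_index = s)
    repr <- simulate_reproduction(design, obs, cond,
                                  subject = subjects[s], subject_index = s)
    readr::write_csv(disc, file.path(dir, "trials",
      paste0("discrimination_", subjects[s], "_", cond, ".csv")))
    readr::write_csv(repr, file.path(dir, "trials",
      paste0("reproduction_", subjects[s], "_", cond, ".csv")))
    pf <- fit_cumulative_normal(disc)
    cf <- fit_central_tendency(repr)
    list(
      disc = dplyr::bind_cols(
        tibble::tibble(subject = subjects[s], condition = cond), glance(pf)
      ),
      repr = dplyr::bind_cols(
        tibble::tibble(subject = subjects[s], condition = cond), glance(cf)
      )
    )
  })
  disc_fits <- dplyr::bind_rows(purrr::map(fits, "disc"))
  repr_fits <- dplyr::bind_rows(purrr::map(fits, "repr"))
  readr::write_csv(disc_fits, file.path(dir, "fits", "discrimination_fits.csv"))
  readr::write_csv(repr_fits, file.path(dir, "fits", "reproduction_fits.csv"))
  say("bayestime: fitted ", nrow(disc_fits), " psychometric and ",
      nrow(repr_fits), " reproduction cells")

  # --- prior widths per subject x condition -----------------------------
  measures <- dplyr::inner_join(
    dplyr::select(disc_fits, "subject", "condition", wf = "weber_fraction"),
    dplyr::select(repr_fits, "subject", "condition", ct = "slope"),
    by = c("subject", "condition")
  ) |>
    dplyr::left_join(design$conditions, by = "condition") |>
    dplyr::mutate(
      # slopes at or above 1 mean no detectable central tendency; clamping
      # keeps the inverted prior width finite (and very large) in that case
      prior_width_ms = estimate_prior_width(
        pmin(pmax(.data$ct, 0.001), 0.999), .data$wf, design$mean_duration_ms
      )
    )
  readr::write_csv(
    dplyr::select(measures, "subject", "condition", "modality", "wf", "ct",
                  "prior_width_ms"),
    file.path(dir, "models", "prior_widths.csv")
  )

  # --- audiovisual predictions under both architectures -----------------
  av_rows <- dplyr::filter(measures, .data$modality == "AV")
  av_pred <- purrr::pmap_dfr(
    dplyr::select(av_rows, "subject", "condition", "vis_noise", "aud_noise",
                  measured_av_wf = "wf", measured_av_slope = "ct"),
    function(subject, condition, vis_noise, aud_noise,
             measured_av_wf, measured_av_slope) {
      uni <- function(mod, noise) {
        dplyr::filter(measures, .data$subject == !!subject,
                      .data$condition == condition_id(
                        mod,
                        if (mod == "V") noise else "none",
                        if (mod == "A") noise else "none"))
      }
      v <- uni("V", vis_noise)
      a <- uni("A", aud_noise)
      durs <- design$reproduction_levels_ms
      mu_p <- design$mean_duration_ms
      m1 <- predict_model1(
        v$wf, a$wf,
        gaussian_belief(mu_p, v$prior_width_ms),
        gaussian_belief(mu_p, a$prior_width_ms),
        durs
      )
      m2 <- predict_model2(v$wf, a$wf, v$prior_width_ms, a$prior_width_ms,
                           durs, prior_mean_ms = mu_p)
      tibble::tibble(
        subject = subject, condition = condition,
        wf_v = v$wf, wf_a = a$wf,
        prior_v_sd = v$prior_width_ms, prior_a_sd = a$prior_width_ms,
        measured_av_wf = measured_av_wf,
        predicted_av_wf = m2$predicted_av_wf,
        measured_av_slope = measured_av_slope,
        model1_slope = m1$predicted_av_slope,
        model2_slope = m2$predicted_av_slope
      )
    }
  )
  readr::write_csv(av_pred, file.path(dir, "models", "av_predictions.csv"))

  # --- statistics -------------------------------------------------------
  stats_out <- compute_run_stats(measures, av_pred, config)
  jsonlite::write_json(stats_out, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  save_run_config(config, file.path(dir, "config.yaml"))
  writeLines(
    c(paste0("bayestime version: ", as.character(utils::packageVersion("bayestime"))),
      paste0("run seed: ", config$seed),
      paste0("subject seeds: ",
             paste(purrr::map_int(cohort, "seed"), collapse = ", "))),
    file.path(dir, "manifest.txt")
  )
  writeLines(report(dir), file.path(dir, "report.md"))
  say("bayestime: run complete at ", dir)
  invisible(dir)
}

# condition contrasts and model-comparison statistics for a completed run
compute_run_stats <- function(measures, av_pred, config) {
  av_conds <- unique(av_pred$condition)

  wf_uni <- dplyr::rename(av_pred, wfbest_v = "wf_v", wfbest_a = "wf_a")
  ct_uni <- av_pred |>
    dplyr::mutate(
      ctbest_v = ct_slope_of(measures, .data$subject, "V", .data$condition),
      ctbest_a = ct_slope_of(measures, .data$subject, "A", .data$condition)
    )

  wf_tests <- contrast_table(wf_uni, "measured_av_wf", "wfbest", "lower",
                             av_conds, config)
  ct_tests <- contrast_table(ct_uni, "measured_av_slope", "ctbest", "higher",
                             av_conds, config)

  # predicted vs measured, pooled over subjects x AV conditions
  wf_reg <- regress_pred_vs_meas(av_pred$predicted_av_wf, av_pred$measured_av_wf)
  m1_reg <- regress_pred_vs_meas(av_pred$model1_slope, av_pred$measured_av_slope)
  m2_reg <- regress_pred_vs_meas(av_pred$model2_slope, av_pred$measured_av_slope)
  m1_t <- paired_t(av_pred$model1_slope, av_pred$measured_av_slope)
  m2_t <- paired_t(av_pred$model2_slope, av_pred$measured_av_slope)

  m1_err <- mean(abs(av_pred$model1_slope - av_pred$measured_av_slope))
  m2_err <- mean(abs(av_pred$model2_slope - av_pred$measured_av_slope))

  list(
    wf_av_vs_best_unisensory = wf_tests,
    ct_av_vs_best_unisensory = ct_tests,
    predicted_vs_measured = list(
      wf = as.list(tidy(wf_reg)),
      ct_model1 = c(as.list(tidy(m1_reg)), as.list(m1_t)),
      ct_model2 = c(as.list(tidy(m2_reg)), as.list(m2_t))
    ),
    model_comparison = list(
      model1_mean_abs_error = m1_err,
      model2_mean_abs_error = m2_err,
      selected = if (m2_err <= m1_err) "model2" else "model1"
    )
  )
}

# helper: AV vs best-unisensory bootstrap contrasts with Bonferroni correction
contrast_table <- function(df, av_col, uni_prefix, better, av_conds, config) {
  res <- purrr::map(seq_along(av_conds), function(i) {
    rows <- dplyr::filter(df, .data$condition == av_conds[i])
    x <- rows[[av_col]]
    y <- purrr::map2_dbl(rows[[paste0(uni_prefix, "_v")]],
                         rows[[paste0(uni_prefix, "_a")]],
                         if (better == "lower") min else max)
    bt <- bootstrap_paired_test(
      x, y, n_boot = config$n_boot,
      seed = derive_seed(config$seed, task = if (better == "lower") 5L else 6L,
                         cond_index = i)
    )
    list(condition = av_conds[i], mean_av = mean(x), mean_best_uni = mean(y),
         mean_diff = bt$mean_diff, p_raw = bt$p_value,
         effect_size_d = bt$effect_size_d)
  })
  p_adj <- bonferroni(purrr::map_dbl(res, "p_raw"), m = length(res))
  purrr::map2(res, p_adj, function(r, p) c(r, list(p_bonferroni = p)))
}

# per-subject unisensory CT slope matching the noise component of an AV cell
ct_slope_of <- function(measures, subject, mod, av_condition) {
  purrr::map2_dbl(subject, av_condition, function(s, cond) {
    parts <- strsplit(cond, ".", fixed = TRUE)[[1]]
    noise <- if (mod == "V") parts[2] else parts[3]
    id <- condition_id(mod, if (mod == "V") noise else "none",
                       if (mod == "A") noise else "none")
    measures$ct[measures$subject == s & measures$condition == id]
  })
}

#' Summarize a completed run
#'
#' Reads the artifacts of a [run_experiment()] directory and renders a
#' markdown summary: Weber fractions and central tendencies by condition
#' (mean and SEM over subjects), estimated prior widths per modality, the
#' audiovisual predictions of both architectures, and the test results.
#'
#' @param run_dir Directory written by [run_experiment()].
#' @return The report as a character vector of markdown lines.
#' @export
report <- function(run_dir) {
  needed <- c("fits/discrimination_fits.csv", "fits/reproduction_fits.csv",
              "models/prior_widths.csv", "models/av_predictions.csv",
              "stats.json", "config.yaml")
  missing <- needed[!file.exists(file.path(run_dir, needed))]
  if (length(missing) > 0) {
    abort(paste0("Run directory is missing artifact(s): ",
                 paste(missing, collapse = ", ")))
  }
  disc <- readr::read_csv(file.path(run_dir, "fits", "discrimination_fits.csv"),
                          show_col_types = FALSE)
  repr <- readr::read_csv(file.path(run_dir, "fits", "reproduction_fits.csv"),
                          show_col_types = FALSE)
  priors <- readr::read_csv(file.path(run_dir, "models", "prior_widths.csv"),
                            show_col_types = FALSE)
  av <- readr::read_csv(file.path(run_dir, "models", "av_predictions.csv"),
                        show_col_types = FALSE)
  stats_json <- jsonlite::read_json(file.path(run_dir, "stats.json"))

  sem <- function(x) sd(x) / sqrt(length(x))
  fmt_tbl <- function(df) {
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
    c(header, sep, rows)
  }

  wf_tbl <- disc |>
    dplyr::group_by(condition = .data$condition) |>
    dplyr::summarise(mean_wf = round(mean(.data$weber_fraction), 3),
                     sem_wf = round(sem(.data$weber_fraction), 3),
                     .groups = "drop")
  ct_tbl <- repr |>
    dplyr::group_by(condition = .data$condition) |>
    dplyr::summarise(mean_slope = round(mean(.data$slope), 3),
                     sem_slope = round(sem(.data$slope), 3),
                     n_excluded = sum(.data$n_excluded),
                     .groups = "drop")
  prior_tbl <- priors |>
    dplyr::group_by(modality = .data$modality) |>
    dplyr::summarise(mean_prior_width_ms = round(mean(.data$prior_width_ms,
                                                      na.rm = TRUE), 1),
                     .groups = "drop")
  av_tbl <- av |>
    dplyr::group_by(condition = .data$condition) |>
    dplyr::summarise(
      measured_slope = round(mean(.data$measured_av_slope), 3),
      model1_slope = round(mean(.data$model1_slope), 3),
      model2_slope = round(mean(.data$model2_slope), 3),
      measured_wf = round(mean(.data$measured_av_wf), 3),
      predicted_wf = round(mean(.data$predicted_av_wf), 3),
      .groups = "drop"
    )

  n_av <- sum(grepl("^AV\\.", unique(disc$condition)))
  n_uni <- length(unique(disc$condition)) - n_av

  c(
    "# Simulated timing experiment report",
    "",
    paste0("Subjects: ", dplyr::n_distinct(disc$subject),
           ". Conditions: ", n_uni, " unisensory, ", n_av, " audiovisual."),
    "",
    "## Weber fractions by condition (mean, SEM over subjects)",
    "",
    fmt_tbl(wf_tbl),
    "",
    "## Central-tendency slopes by condition (mean, SEM over subjects)",
    "",
    fmt_tbl(ct_tbl),
    "",
    "## Estimated prior widths by modality (ms)",
    "",
    fmt_tbl(prior_tbl),
    "",
    "## Audiovisual predictions (cohort means)",
    "",
    fmt_tbl(av_tbl),
    "",
    "## Model comparison",
    "",
    paste0("Mean |predicted - measured| AV slope: model1 = ",
           signif(stats_json$model_comparison$model1_mean_abs_error, 3),
           ", model2 = ",
           signif(stats_json$model_comparison$model2_mean_abs_error, 3),
           "; selected: **", stats_json$model_comparison$selected, "**."),
    "",
    paste0("Predicted-vs-measured WF regression: slope = ",
           signif(stats_json$predicted_vs_measured$wf$slope, 3),
           ", r = ", signif(stats_json$predicted_vs_measured$wf$r, 3), ".")
  )
}
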