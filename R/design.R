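#' Experimental design for the timing tasks
#'
#' Builds the design shared by the duration-discrimination and
#' duration-reproduction tasks: a 640-ms standard, comparison/stimulus
#' durations log-spaced between 450 and 900 ms, and the condition grid of
#' modalities (visual, auditory, audiovisual) crossed with background-noise
#' levels. Audiovisual blocks use the three noise combinations of the study
#' design: high/high, high/low and low/high (visual/auditory).
#'
#' @param standard_ms Standard duration for the discrimination task (ms).
#' @param min_ms,max_ms Endpoints of the duration range (ms). Levels are
#'   log-spaced between them.
#' @param n_levels Number of duration levels for both tasks.
#' @param reps_discrimination Presentations of each comparison level.
#' @param reps_reproduction Presentations of each reproduction level.
#' @param comparison_levels_ms,reproduction_levels_ms Optional explicit level
#'   vectors; must be strictly increasing and lie within `[min_ms, max_ms]`.
#' @param mean_type How the mean stimulus duration (the prior center under
#'   the `"auto"` prior mean) is computed from the reproduction levels:
#'   arithmetic (default) or geometric mean.
#'
#' @return An object of class `bt_design`: a list with the level vectors, the
#'   repetition counts, `mean_duration_ms`, and `conditions`, a tibble with
#'   columns `condition`, `modality`, `vis_noise`, `aud_noise` (six unisensory
#'   conditions plus three audiovisual noise combinations).
#'
#' @examples
#' d <- make_design()
#' d$conditions
#' @export
make_design <- function(standard_ms = 640,
                        min_ms = 450,
                        max_ms = 900,
                        n_levels = 7,
                        reps_discrimination = 24,
                        reps_reproduction = 60,
                        comparison_levels_ms = NULL,
                        reproduction_levels_ms = NULL,
                        mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  check_positive_scalar(standard_ms, "standard_ms")
  check_positive_scalar(min_ms, "min_ms")
  check_positive_scalar(max_ms, "max_ms")
  if (max_ms <= min_ms) {
    abort("`max_ms` must exceed `min_ms`.")
  }
  if (n_levels < 2) abort("`n_levels` must be at least 2.")
  if (reps_discrimination < 1) {
    abort("`reps_discrimination` must be a positive integer.")
  }
  if (reps_reproduction < 1) {
    abort("`reps_reproduction` must be a positive integer.")
  }

  log_levels <- exp(seq(log(min_ms), log(max_ms), length.out = n_levels))
  log_levels[c(1, n_levels)] <- c(min_ms, max_ms)
  comparison_levels_ms <- check_levels(
    comparison_levels_ms %||% log_levels, "comparison_levels_ms", min_ms, max_ms
  )
  reproduction_levels_ms <- check_levels(
    reproduction_levels_ms %||% log_levels, "reproduction_levels_ms", min_ms, max_ms
  )

  mean_duration_ms <- switch(mean_type,
    arithmetic = mean(reproduction_levels_ms),
    geometric  = exp(mean(log(reproduction_levels_ms)))
  )

  uni <- tidyr::expand_grid(
    modality = c("V", "A"),
    noise = c("no", "low", "high")
  )
  conditions <- dplyr::bind_rows(
    tibble::tibble(
      modality = uni$modality,
      vis_noise = ifelse(uni$modality == "V", uni$noise, "none"),
      aud_noise = ifelse(uni$modality == "A", uni$noise, "none")
    ),
    tibble::tibble(
      modality = "AV",
      vis_noise = c("high", "high", "low"),
      aud_noise = c("high", "low", "high")
    )
  )
  conditions <- dplyr::mutate(
    conditions,
    condition = condition_id(.data$modality, .data$vis_noise, .data$aud_noise),
    .before = 1
  )

  structure(
    list(
      standard_ms = standard_ms,
      comparison_levels_ms = comparison_levels_ms,
      reproduction_levels_ms = reproduction_levels_ms,
      reps_discrimination = as.integer(reps_discrimination),
      reps_reproduction = as.integer(reps_reproduction),
      mean_type = mean_type,
      mean_duration_ms = mean_duration_ms,
      conditions = conditions
    ),
    class = "bt_design"
  )
}

#' @export
print.bt_design <- function(x, ...) {
  cat("<bt_design>\n")
  cat("  standard:", x$standard_ms, "ms\n")
  cat("  levels:", paste(round(x$comparison_levels_ms), collapse = ", "), "ms\n")
  cat("  reps: ", x$reps_discrimination, " (discrimination), ",
      x$reps_reproduction, " (reproduction)\n", sep = "")
  cat("  mean duration:", round(x$mean_duration_ms, 1), "ms (", x$mean_type, ")\n")
  cat("  conditions:", nrow(x$conditions), "\n")
  invisible(x)
}

#' Condition identifier
#'
#' Conditions are labelled `"<modality>.<vis_noise>.<aud_noise>"`, with
#' `"none"` for the absent channel of a unisensory condition, e.g.
#' `"V.low.none"` or `"AV.high.low"`.
#'
#' @param modality `"V"`, `"A"` or `"AV"`.
#' @param vis_noise,aud_noise Noise levels (`"no"`, `"low"`, `"high"`, or
#'   `"none"` for an absent channel).
#' @return Character vector of condition ids.
#' @export
condition_id <- function(modality, vis_noise, aud_noise) {
  paste(modality, vis_noise, aud_noise, sep = ".")
}

# resolve a condition id to its row of design$conditions
lookup_condition <- function(design, condition) {
  stopifnot(inherits(design, "bt_design"))
  i <- match(condition, design$conditions$condition)
  if (length(condition) != 1L || is.na(i)) {
    abort(paste0(
      "Unknown condition ", paste0("'", condition, "'", collapse = ", "),
      ". Known conditions: ",
      paste(design$conditions$condition, collapse = ", ")
    ))
  }
  dplyr::slice(design$conditions, i)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(paste0("`", name, "` must be a positive finite number."))
  }
  invisible(x)
}

check_levels <- function(levels, name, min_ms, max_ms) {
  if (any(diff(levels) <= 0)) {
    abort(paste0("`", name, "` must be strictly increasing."))
  }
  tol <- 1e-8 * max_ms
  if (any(levels < min_ms - tol) || any(levels > max_ms + tol)) {
    abort(paste0("`", name, "` must lie within [", min_ms, ", ", max_ms, "] ms."))
  }
  as.numeric(levels)
}
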