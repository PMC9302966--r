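#' Mean of a trajectory over a half-open time window
#'
#' Averages the samples with `t0_ms <= t < t1_ms` (time measured from vowel
#' onset). If the trajectory covers less than `min_coverage` of the window's
#' grid points — typically because the vowel ended early — the value is
#' missing rather than resting on a sliver of data.
#'
#' @param f1 A numeric trajectory.
#' @param step_ms Sampling step.
#' @param t0_ms,t1_ms Window bounds in ms, `t0_ms < t1_ms`; the window is
#'   half-open `[t0, t1)`.
#' @param min_coverage Minimum fraction of the window's grid points that must
#'   carry samples (default 0.5).
#' @return The window mean in mels, or `NA_real_` under insufficient coverage.
#' @export
window_mean <- function(f1, step_ms, t0_ms, t1_ms, min_coverage = 0.5) {
  if (t0_ms >= t1_ms) abort("`t0_ms` must be < `t1_ms`.")
  t <- traj_times(f1, step_ms)
  idx <- t >= t0_ms & t < t1_ms
  # grid points of the full window, whether sampled or not
  first_k <- ceiling(t0_ms / step_ms - 1e-9)
  last_k <- ceiling(t1_ms / step_ms - 1e-9) - 1
  expected <- max(0L, last_k - first_k + 1L)
  if (expected == 0L || sum(idx) / expected < min_coverage) return(NA_real_)
  mean(f1[idx])
}

#' Trial-level windowed responses
#'
#' Computes one scalar response per normalized trial: the mean normalized F1
#' over the measure's analysis window. For `measure = "compensation"` the
#' input must be perturbed trials and the default window is 150-250 ms after
#' vowel onset (past the typical onset latency of the online response). For
#' `measure = "adaptation"` the input must be post-perturbation trials, the
#' default window is the first 100 ms (before auditory feedback can act on
#' the current trial), and the trial's direction is the direction of the
#' preceding trial's perturbation.
#'
#' @param normalized Output `$trials` of [normalize_trials()] on a labeled
#'   table, restricted by the caller to the appropriate role.
#' @param measure `"compensation"` or `"adaptation"`.
#' @param window Length-2 numeric window in ms; `NULL` uses the measure's
#'   default (`c(150, 250)` or `c(0, 100)`; an alternative adaptation window
#'   `c(50, 150)` skips the consonant transition).
#' @param min_coverage Passed to [window_mean()].
#' @return A response table: one row per trial with `direction`, `measure`,
#'   `window_t0_ms`, `window_t1_ms`, `value_mels`, `sign_corrected = FALSE`,
#'   `shift_magnitude_mels` (the shift that defines the direction: the
#'   trial's own for compensation, the previous trial's for adaptation), and
#'   `prev_trial_index` for adaptation rows. Rows with insufficient window
#'   coverage carry `NA` values.
#' @export
trial_responses <- function(normalized, measure = c("compensation", "adaptation"),
                            window = NULL, min_coverage = 0.5) {
  measure <- match.arg(measure)
  window <- window %||% default_window(measure)
  if (measure == "compensation") {
    ok <- normalized$perturbed_up | normalized$perturbed_down
    if (!all(ok)) abort("Compensation responses are defined only for perturbed trials.")
    direction <- ifelse(normalized$perturbed_up, "up", "down")
    magnitude <- normalized$shift_magnitude_mels
    prev_idx <- rep(NA_integer_, nrow(normalized))
  } else {
    ok <- normalized$post_up | normalized$post_down
    if (!all(ok)) abort("Adaptation responses are defined only for post-perturbation trials.")
    direction <- ifelse(normalized$post_up, "up", "down")
    magnitude <- normalized$prev_shift_magnitude_mels
    prev_idx <- normalized$prev_trial_index
  }
  tibble::tibble(
    study_id = normalized$study_id,
    participant_id = normalized$participant_id,
    trial_index = normalized$trial_index,
    direction = direction,
    measure = measure,
    window_t0_ms = window[1],
    window_t1_ms = window[2],
    value_mels = vapply(
      normalized$norm, window_mean, numeric(1),
      step_ms = normalized$step_ms[1], t0_ms = window[1], t1_ms = window[2],
      min_coverage = min_coverage
    ),
    sign_corrected = FALSE,
    shift_magnitude_mels = magnitude,
    prev_trial_index = as.integer(prev_idx)
  )
}

default_window <- function(measure) {
  switch(measure, compensation = c(150, 250), adaptation = c(0, 100))
}

#' Participant condition-average trajectory
#'
#' Pointwise mean of a participant's normalized trajectories for one
#' condition (e.g. all up-perturbed trials), with the same minimum-count
#' truncation rule as [baseline_trajectory()] but defaulting to `min_n = 1`
#' (a single trial is a legitimate, if noisy, condition average).
#'
#' @param norm_list List of normalized trajectories.
#' @param min_n Minimum contributing trials per retained time point.
#' @return A numeric trajectory, or `NULL` if `norm_list` is empty.
#' @export
participant_average_trajectory <- function(norm_list, min_n = 1) {
  if (length(norm_list) == 0) return(NULL)
  m <- traj_matrix(norm_list)
  n_at <- colSums(!is.na(m))
  keep <- which(n_at >= min_n)
  if (length(keep) == 0) return(NULL)
  colMeans(m[, seq_len(max(keep)), drop = FALSE], na.rm = TRUE)
}

#' Participant-level windowed responses
#'
#' Computes the participant-level response for each (participant, direction):
#' the window mean of the participant's condition-average trajectory
#' (average-then-window, which with unequal vowel lengths is not the same as
#' averaging trial-level window means).
#'
#' @param normalized As in [trial_responses()].
#' @param measure,window,min_coverage As in [trial_responses()].
#' @param min_n Passed to [participant_average_trajectory()].
#' @return A response table with `trial_index = NA` and one row per
#'   (study, participant, direction); participants lacking trials for a
#'   direction or window coverage get `NA` values.
#' @export
participant_responses <- function(normalized,
                                  measure = c("compensation", "adaptation"),
                                  window = NULL, min_coverage = 0.5,
                                  min_n = 1) {
  measure <- match.arg(measure)
  window <- window %||% default_window(measure)
  if (measure == "compensation") {
    direction <- ifelse(normalized$perturbed_up, "up", "down")
    normalized$.mag <- normalized$shift_magnitude_mels
  } else {
    direction <- ifelse(normalized$post_up, "up", "down")
    normalized$.mag <- normalized$prev_shift_magnitude_mels
  }
  normalized$direction <- direction
  step <- normalized$step_ms[1]
  normalized |>
    dplyr::group_by(.data$study_id, .data$participant_id, .data$direction) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      shift_magnitude_mels = mean(.data$.mag, na.rm = TRUE),
      value_mels = {
        avg <- participant_average_trajectory(.data$norm, min_n = min_n)
        if (is.null(avg)) NA_real_ else {
          window_mean(avg, step, window[1], window[2], min_coverage)
        }
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      trial_index = NA_integer_,
      measure = measure,
      window_t0_ms = window[1],
      window_t1_ms = window[2],
      sign_corrected = FALSE,
      prev_trial_index = NA_integer_
    )
}

#' Sign-correct responses
#'
#' Multiplies responses from upward-shift conditions by -1 so that both
#' directions share a common scale on which positive values oppose the
#' applied shift. Refuses to run twice.
#'
#' @param rows A response table ([trial_responses()] or
#'   [participant_responses()]).
#' @return The table with up-direction values negated and
#'   `sign_corrected = TRUE`.
#' @export
sign_correct <- function(rows) {
  if (any(rows$sign_corrected)) abort("Responses are already sign-corrected.")
  rows$value_mels <- ifelse(
    rows$direction == "up", -rows$value_mels, rows$value_mels
  )
  rows$sign_corrected <- TRUE
  rows
}
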