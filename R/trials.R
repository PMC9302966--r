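#' Build a trial table
#'
#' The central data structure is a tibble with one row per utterance (trial)
#' and the F1 trajectory stored as a list-column of numeric vectors in mels.
#' Sample `k` of a trajectory (1-based) is the F1 value at time
#' `(k - 1) * step_ms` after vowel onset, so every trajectory starts at t = 0
#' on a uniform grid.
#'
#' Required columns:
#' \describe{
#'   \item{study_id, participant_id}{identifiers (coerced to character).}
#'   \item{trial_index}{session order, integer >= 1, unique within a
#'     (study, participant) session.}
#'   \item{word}{the spoken word.}
#'   \item{perturbation}{`"none"`, `"up"`, or `"down"`.}
#'   \item{shift_magnitude_mels}{magnitude of the applied F1 shift; 0 if and
#'     only if `perturbation == "none"`.}
#'   \item{vowel_duration_ms}{measured vowel duration.}
#'   \item{step_ms}{trajectory sampling step (constant across the table).}
#'   \item{f1}{list-column of numeric F1 trajectories (mels).}
#' }
#'
#' @param x A data frame with the columns above.
#' @return A validated tibble of trials.
#' @seealso [read_trials()], [simulate_experiment()]
#' @export
as_trial_table <- function(x) {
  required <- c(
    "study_id", "participant_id", "trial_index", "word", "perturbation",
    "shift_magnitude_mels", "vowel_duration_ms", "step_ms", "f1"
  )
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing trial columns: ", paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(x)
  out$study_id <- as.character(out$study_id)
  out$participant_id <- as.character(out$participant_id)
  out$trial_index <- as.integer(out$trial_index)
  out$word <- as.character(out$word)
  out$perturbation <- as.character(out$perturbation)
  validate_trials(out)
  out
}

#' Validate a trial table
#'
#' Checks the structural invariants of a trial table: enum values, positive
#' durations, the `shift_magnitude_mels`/`perturbation` coupling, finite
#' trajectories no longer than the vowel plus one sampling step, a single
#' sampling step across the table, and unique trial indices within each
#' (study, participant) session.
#'
#' @param trials A trial table (see [as_trial_table()]).
#' @return `trials`, invisibly. Errors describe the first offending trial.
#' @export
validate_trials <- function(trials) {
  bad_enum <- !trials$perturbation %in% c("none", "up", "down")
  if (any(bad_enum)) {
    abort(paste0(
      "Invalid perturbation value(s): ",
      paste(unique(trials$perturbation[bad_enum]), collapse = ", ")
    ))
  }
  if (any(trials$trial_index < 1L)) abort("`trial_index` must be >= 1.")
  if (any(!is.finite(trials$vowel_duration_ms)) ||
      any(trials$vowel_duration_ms <= 0)) {
    abort("`vowel_duration_ms` must be positive and finite.")
  }
  if (length(unique(trials$step_ms)) > 1) {
    abort("`step_ms` must be constant across the trial table.")
  }
  if (any(trials$step_ms <= 0)) abort("`step_ms` must be positive.")
  shift0 <- trials$shift_magnitude_mels == 0
  if (any(shift0 != (trials$perturbation == "none"))) {
    abort("`shift_magnitude_mels` must be 0 exactly for unperturbed trials and > 0 otherwise.")
  }
  len <- lengths(trials$f1)
  if (any(len < 1L)) abort("Every trajectory needs at least one sample.")
  too_long <- len * trials$step_ms > trials$vowel_duration_ms + trials$step_ms
  if (any(too_long)) {
    abort(paste0(
      "Trajectory longer than vowel for trial ",
      format_trial_id(trials[which(too_long)[1], ])
    ))
  }
  if (any(!vapply(trials$f1, function(v) all(is.finite(v)), logical(1)))) {
    abort("All trajectory values must be finite.")
  }
  dup <- duplicated(trials[, c("study_id", "participant_id", "trial_index")])
  if (any(dup)) {
    abort(paste0(
      "Duplicate trial_index within session: ",
      format_trial_id(trials[which(dup)[1], ])
    ))
  }
  invisible(trials)
}

format_trial_id <- function(row) {
  paste0(
    "study=", row$study_id, ", participant=", row$participant_id,
    ", trial=", row$trial_index
  )
}

#' Trajectory time grid
#'
#' @param f1 A numeric trajectory.
#' @param step_ms Sampling step in ms.
#' @return Times (ms from vowel onset) of the samples of `f1`.
#' @export
traj_times <- function(f1, step_ms) (seq_along(f1) - 1) * step_ms

# Stack a list of trajectories into a trials x time matrix, padding with NA.
traj_matrix <- function(f1_list, ncol = max(lengths(f1_list))) {
  out <- matrix(NA_real_, nrow = length(f1_list), ncol = ncol)
  len <- pmin(lengths(f1_list), ncol)
  for (i in seq_along(f1_list)) {
    out[i, seq_len(len[i])] <- f1_list[[i]][seq_len(len[i])]
  }
  out
}

#' Read a long-format trial table
#'
#' Reads a CSV/TSV file with one row per trajectory sample and the columns
#' `study_id, participant_id, trial_index, word, perturbation,
#' shift_magnitude_mels, vowel_duration_ms, time_ms` plus an F1 column whose
#' unit is declared either by its name (`f1_mels` or `f1_hz`) or by the
#' `units` argument for a bare `f1` column. Hz values are converted to mels
#' on read. Within each trial the time grid must start at 0 and be uniform;
#' violations are reported with the offending trial.
#'
#' @param path Path to a delimited text file.
#' @param units Unit of a bare `f1` column: `"mels"` or `"hz"`. Ignored when
#'   the file has an `f1_mels` or `f1_hz` column.
#' @param delim Field delimiter (default `","`).
#' @return A trial table (see [as_trial_table()]).
#' @export
read_trials <- function(path, units = c("mels", "hz"), delim = ",") {
  units <- match.arg(units)
  raw <- readr::read_delim(
    path,
    delim = delim, show_col_types = FALSE, progress = FALSE
  )
  f1_col <- intersect(c("f1_mels", "f1_hz", "f1"), names(raw))[1]
  if (is.na(f1_col)) abort("No F1 column (`f1`, `f1_mels`, or `f1_hz`) found.")
  required <- c(
    "study_id", "participant_id", "trial_index", "word", "perturbation",
    "shift_magnitude_mels", "vowel_duration_ms", "time_ms"
  )
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  in_hz <- f1_col == "f1_hz" || (f1_col == "f1" && units == "hz")
  raw$..f1 <- if (in_hz) hz_to_mel(raw[[f1_col]]) else raw[[f1_col]]

  if (nrow(raw) == 0) {
    return(as_trial_table(tibble::tibble(
      study_id = character(), participant_id = character(),
      trial_index = integer(), word = character(),
      perturbation = character(), shift_magnitude_mels = numeric(),
      vowel_duration_ms = numeric(), step_ms = numeric(), f1 = list()
    )))
  }

  key <- c("study_id", "participant_id", "trial_index")
  dup <- duplicated(raw[, c(key, "time_ms")])
  if (any(dup)) {
    bad <- raw[which(dup)[1], ]
    abort(paste0(
      "Duplicate sample at time_ms=", bad$time_ms, " for ",
      format_trial_id(bad), " (row ", which(dup)[1], ")"
    ))
  }

  trials <- raw |>
    dplyr::arrange(
      .data$study_id, .data$participant_id, .data$trial_index, .data$time_ms
    ) |>
    dplyr::group_by(
      .data$study_id, .data$participant_id, .data$trial_index,
      .data$word, .data$perturbation, .data$shift_magnitude_mels,
      .data$vowel_duration_ms
    ) |>
    dplyr::summarise(
      step_ms = check_grid(.data$time_ms, dplyr::cur_group()),
      f1 = list(.data$..f1),
      .groups = "drop"
    )
  steps <- unique(trials$step_ms[!is.na(trials$step_ms)])
  if (length(steps) > 1) {
    abort("Trials disagree on the sampling step; a single grid is required.")
  }
  # single-sample trials carry no step information; adopt the table's step
  trials$step_ms[is.na(trials$step_ms)] <- if (length(steps) > 0) steps else 1
  as_trial_table(trials)
}

check_grid <- function(time_ms, group) {
  id <- paste0(
    "study=", group$study_id, ", participant=", group$participant_id,
    ", trial=", group$trial_index
  )
  if (time_ms[1] != 0) {
    abort(paste0("Time grid does not start at 0 for ", id))
  }
  if (length(time_ms) == 1) return(NA_real_)
  d <- diff(time_ms)
  if (any(abs(d - d[1]) > 1e-9) || d[1] <= 0) {
    abort(paste0("Non-uniform time grid for ", id))
  }
  d[1]
}

#' Write a trial table to long-format CSV
#'
#' Inverse of [read_trials()]: one row per sample, F1 written in mels as an
#' `f1_mels` column. `read_trials(write_trials(x, path))` reproduces `x`
#' (metadata exactly, values to numeric print precision).
#'
#' @param trials A trial table.
#' @param path Output path.
#' @param delim Field delimiter (default `","`).
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, delim = ",") {
  validate_trials(trials)
  long <- tidyr::unnest(
    dplyr::mutate(
      trials,
      time_ms = purrr::map2(.data$f1, .data$step_ms, traj_times),
      f1_mels = .data$f1,
      f1 = NULL, step_ms = NULL
    ),
    cols = c("time_ms", "f1_mels")
  )
  readr::write_delim(long, path, delim = delim, progress = FALSE)
  invisible(path)
}
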