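#' Label trials by their analysis role
#'
#' Adds the role flags the analysis is built on. Within each
#' (study, participant) session, ordered by `trial_index` with adjacency
#' meaning consecutive indices:
#' \describe{
#'   \item{perturbed_up / perturbed_down}{trials carrying a shift; used for
#'     compensation.}
#'   \item{post_up / post_down}{unperturbed trials directly after an up/down
#'     perturbed trial; used for one-shot adaptation.}
#'   \item{baseline_comp}{all unperturbed trials — the baseline pool for the
#'     compensation analysis.}
#'   \item{baseline_adapt}{unperturbed trials directly after another
#'     unperturbed trial — the (stricter) baseline pool for the adaptation
#'     analysis, a subset of `baseline_comp`.}
#' }
#' The first trial of a session is never `post_*` or `baseline_adapt`, and a
#' trial whose predecessor index is absent from the table (a gap) is treated
#' as having no known predecessor. Columns `prev_perturbation`,
#' `prev_shift_magnitude_mels` and `prev_trial_index` record the adjacent
#' predecessor where one exists.
#'
#' @param trials A trial table.
#' @return `trials` with the label columns appended.
#' @export
label_trials <- function(trials) {
  validate_trials(trials)
  trials |>
    dplyr::arrange(.data$study_id, .data$participant_id, .data$trial_index) |>
    dplyr::group_by(.data$study_id, .data$participant_id) |>
    dplyr::mutate(
      .prev_idx = dplyr::lag(.data$trial_index),
      .adjacent = !is.na(.data$.prev_idx) &
        .data$.prev_idx == .data$trial_index - 1L,
      prev_perturbation = ifelse(
        .data$.adjacent, dplyr::lag(.data$perturbation), NA_character_
      ),
      prev_shift_magnitude_mels = ifelse(
        .data$.adjacent, dplyr::lag(.data$shift_magnitude_mels), NA_real_
      ),
      prev_trial_index = ifelse(.data$.adjacent, .data$.prev_idx, NA_integer_),
      perturbed_up = .data$perturbation == "up",
      perturbed_down = .data$perturbation == "down",
      post_up = .data$perturbation == "none" & .data$.adjacent &
        .data$prev_perturbation == "up",
      post_down = .data$perturbation == "none" & .data$.adjacent &
        .data$prev_perturbation == "down",
      baseline_comp = .data$perturbation == "none",
      baseline_adapt = .data$perturbation == "none" & .data$.adjacent &
        .data$prev_perturbation == "none"
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".prev_idx", -".adjacent")
}

#' Exclude trials with short vowels
#'
#' Vowels shorter than `min_ms` carry too little of the analysis windows and
#' are dropped (the emulated studies dropped vowels under 100 ms, < 1% of
#' trials). The boundary is inclusive: a vowel of exactly `min_ms` is kept.
#'
#' @param trials A trial table.
#' @param min_ms Minimum vowel duration in ms (default 100).
#' @return A list with `kept` and `dropped` trial tables and the counts
#'   `n_kept`, `n_dropped`.
#' @export
filter_short_vowels <- function(trials, min_ms = 100) {
  if (min_ms < 0) abort("`min_ms` must be >= 0.")
  keep <- trials$vowel_duration_ms >= min_ms
  list(
    kept = trials[keep, , drop = FALSE],
    dropped = trials[!keep, , drop = FALSE],
    n_kept = sum(keep),
    n_dropped = sum(!keep)
  )
}

#' Pointwise-mean baseline trajectory
#'
#' Averages a set of trajectories sample-by-sample. At each time point the
#' mean is taken over the trajectories that reach it; the result is truncated
#' at the last time point where at least `min_n` trajectories contribute, so
#' the tail of the baseline never rests on one or two long vowels.
#'
#' @param f1_list List of numeric trajectories on a shared grid.
#' @param min_n Minimum number of contributing trials per retained time point.
#' @param id Optional label used in error messages.
#' @return A numeric baseline trajectory.
#' @export
baseline_trajectory <- function(f1_list, min_n = 3, id = NULL) {
  if (length(f1_list) < min_n) {
    abort(paste0(
      "Fewer than min_n = ", min_n, " baseline trials",
      if (!is.null(id)) paste0(" for ", id) else ""
    ))
  }
  m <- traj_matrix(f1_list)
  n_at <- colSums(!is.na(m))
  keep <- which(n_at >= min_n)
  if (length(keep) == 0 || keep[1] != 1L) {
    abort(paste0(
      "Fewer than min_n = ", min_n, " baseline trials at vowel onset",
      if (!is.null(id)) paste0(" for ", id) else ""
    ))
  }
  last <- max(keep)
  colMeans(m[, seq_len(last), drop = FALSE], na.rm = TRUE)
}

#' Compute participant- and word-specific baseline trajectories
#'
#' Builds one baseline per (study, participant, word) by pointwise-averaging
#' that pair's baseline-role trials ([baseline_trajectory()]). For the
#' compensation analysis the baseline pool is all unperturbed trials
#' (`role = "comp"`); for the adaptation analysis it is unperturbed trials
#' following unperturbed trials (`role = "adapt"`). Post-perturbation trials
#' are unperturbed and therefore sit in the compensation pool by default;
#' `include_post_trials = FALSE` removes them so that one-shot adaptation
#' cannot leak into the compensation baseline.
#'
#' @param labeled A labeled trial table ([label_trials()]).
#' @param role `"comp"` or `"adapt"`.
#' @param min_n Minimum trials per retained baseline time point.
#' @param include_post_trials Keep post-perturbation trials in the `"comp"`
#'   pool (default `TRUE`).
#' @return A tibble (`study_id`, `participant_id`, `word`, `n_baseline`,
#'   `baseline` list-column). Pairs with fewer than `min_n` baseline trials
#'   are omitted (downstream trials of such pairs are dropped and counted).
#' @export
compute_baselines <- function(labeled, role = c("comp", "adapt"), min_n = 3,
                              include_post_trials = TRUE) {
  role <- match.arg(role)
  pool <- if (role == "comp") labeled$baseline_comp else labeled$baseline_adapt
  if (role == "comp" && !include_post_trials) {
    pool <- pool & !labeled$post_up & !labeled$post_down
  }
  labeled[pool, ] |>
    dplyr::group_by(.data$study_id, .data$participant_id, .data$word) |>
    dplyr::summarise(
      n_baseline = dplyr::n(),
      baseline = list(if (dplyr::n() >= min_n) {
        baseline_trajectory(.data$f1, min_n = min_n)
      }),
      .groups = "drop"
    ) |>
    dplyr::filter(!vapply(.data$baseline, is.null, logical(1)))
}

#' Normalize a trajectory against a baseline
#'
#' @param f1 A trial trajectory.
#' @param baseline The matching baseline trajectory on the same grid.
#' @return `f1 - baseline` over the common time support (deviation in mels).
#' @export
normalize_trajectory <- function(f1, baseline) {
  n <- min(length(f1), length(baseline))
  if (n == 0) abort("Trial and baseline share no time support.")
  f1[seq_len(n)] - baseline[seq_len(n)]
}

#' Normalize a set of trials against participant- and word-specific baselines
#'
#' Joins trials to the baselines of their (study, participant, word) and
#' expresses each trajectory as its deviation from the baseline mean
#' trajectory. Trials whose pair has no baseline are dropped and counted.
#'
#' @param trials A (labeled) trial table.
#' @param baselines Output of [compute_baselines()].
#' @return A list with `trials` (input rows that found a baseline, plus a
#'   `norm` list-column of normalized trajectories) and `n_no_baseline`.
#' @export
normalize_trials <- function(trials, baselines) {
  joined <- dplyr::left_join(
    trials, baselines,
    by = c("study_id", "participant_id", "word")
  )
  has_base <- !vapply(joined$baseline, is.null, logical(1))
  kept <- joined[has_base, , drop = FALSE]
  kept$norm <- purrr::map2(kept$f1, kept$baseline, normalize_trajectory)
  kept$baseline <- NULL
  list(trials = kept, n_no_baseline = sum(!has_base))
}

#' Screen out outlier participants
#'
#' Single, non-iterative screen on participant-session averages: a session is
#' excluded when its average (sign-corrected, direction-collapsed)
#' compensation or one-shot adaptation lies more than `k_sd` standard
#' deviations from the across-session mean of that measure. Means and SDs are
#' computed once over all sessions; if a measure has zero SD nobody is
#' excluded on it.
#'
#' @param responses Tibble with one row per participant session and columns
#'   `study_id`, `participant_id`, `compensation`, `adaptation`.
#' @param k_sd Exclusion threshold in SD units (default 4).
#' @return A list with `kept`, `excluded` (with a `flagged_on` column), and
#'   the per-measure means/SDs used.
#' @export
exclude_outlier_participants <- function(responses, k_sd = 4) {
  stopifnot(k_sd > 0)
  if (nrow(responses) < 3) abort("Outlier screening needs >= 3 participant sessions.")
  z_of <- function(x) {
    s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x, na.rm = TRUE)) / s
  }
  z_comp <- z_of(responses$compensation)
  z_adapt <- z_of(responses$adaptation)
  out_comp <- !is.na(z_comp) & abs(z_comp) > k_sd
  out_adapt <- !is.na(z_adapt) & abs(z_adapt) > k_sd
  flagged <- out_comp | out_adapt
  excluded <- responses[flagged, , drop = FALSE]
  excluded$flagged_on <- dplyr::case_when(
    out_comp[flagged] & out_adapt[flagged] ~ "both",
    out_comp[flagged] ~ "compensation",
    TRUE ~ "adaptation"
  )
  list(
    kept = responses[!flagged, , drop = FALSE],
    excluded = excluded,
    stats = tibble::tibble(
      measure = c("compensation", "adaptation"),
      mean = c(mean(responses$compensation, na.rm = TRUE),
               mean(responses$adaptation, na.rm = TRUE)),
      sd = c(sd(responses$compensation, na.rm = TRUE),
             sd(responses$adaptation, na.rm = TRUE))
    )
  )
}
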