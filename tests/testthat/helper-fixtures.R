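# Shared fixture builders for the test suite.

# A minimal trial table from a perturbation sequence; trajectories are
# constant at `value` unless a list of trajectories is given.
make_trials <- function(perturbation,
                        f1 = NULL,
                        value = 700,
                        word = "bed",
                        duration_ms = 300,
                        step_ms = 5,
                        magnitude = 125,
                        participant = "p1",
                        study = "s1",
                        trial_index = seq_along(perturbation)) {
  n <- length(perturbation)
  if (is.null(f1)) {
    len <- floor(duration_ms / step_ms) + 1
    f1 <- replicate(n, rep(value, len), simplify = FALSE)
  }
  as_trial_table(tibble::tibble(
    study_id = study,
    participant_id = participant,
    trial_index = trial_index,
    word = rep_len(word, n),
    perturbation = perturbation,
    shift_magnitude_mels = ifelse(perturbation == "none", 0, magnitude),
    vowel_duration_ms = rep_len(duration_ms, n),
    step_ms = step_ms,
    f1 = f1
  ))
}

# A noise-free simulator configuration (deterministic trajectories).
quiet_sim <- function(...) {
  sim_config(
    baseline_participant_sd_mels = 0,
    baseline_word_sd_mels = 0,
    noise_trial_sd_mels = 0,
    noise_sample_sd_mels = 0,
    comp_gain_sd = 0,
    adapt_gain_sd = 0,
    gain_correlation = 0,
    short_vowel_frac = 0,
    ...
  )
}

# Reduced analysis chain used by simulation-heavy tests: trial and
# participant responses (optionally models) without the permutation tests.
quick_responses <- function(trials, comp_window = c(150, 250),
                            adapt_window = c(0, 100), min_n = 3) {
  lab <- filter_short_vowels(label_trials(trials))$kept
  base_comp <- compute_baselines(lab, "comp", min_n = min_n)
  base_adapt <- compute_baselines(lab, "adapt", min_n = min_n)
  norm_comp <- normalize_trials(
    lab[lab$perturbed_up | lab$perturbed_down, ], base_comp
  )$trials
  norm_adapt <- normalize_trials(lab[lab$post_up | lab$post_down, ], base_adapt)$trials
  list(
    labeled = lab,
    norm_comp = norm_comp,
    norm_adapt = norm_adapt,
    comp_trial = trial_responses(norm_comp, "compensation", window = comp_window),
    adapt_trial = trial_responses(norm_adapt, "adaptation", window = adapt_window),
    comp_ppt = participant_responses(norm_comp, "compensation", window = comp_window),
    adapt_ppt = participant_responses(norm_adapt, "adaptation", window = adapt_window)
  )
}
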