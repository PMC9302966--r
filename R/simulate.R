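#' Configuration for the synthetic experiment generator
#'
#' Builds a validated configuration for [simulate_experiment()]. Defaults
#' describe a session in the style of the formant-perturbation studies the
#' package analyzes: monosyllabic /E/ words, 120 trials of which half carry
#' an unpredictable +/- 125 mel F1 shift, vowels mostly 150-350 ms long, and
#' small opposing responses — an online compensation that ramps up ~120 ms
#' after vowel onset on perturbed trials, and a one-shot adaptation carried
#' as a constant offset into the single following trial.
#'
#' Effect sizes are expressed as gains, i.e. the fraction of the applied
#' shift that the response opposes. Each participant draws a
#' (compensation gain, adaptation gain) pair from a bivariate normal with
#' correlation `gain_correlation`.
#'
#' @param n_participants Participants per study.
#' @param n_studies Number of studies (participants are nested in studies).
#' @param words Word list cycled pseudorandomly over trials.
#' @param n_trials Trials per session.
#' @param p_perturbed Fraction of perturbed trials (0-1; studies used 0.25-0.5).
#' @param shift_mean_mels,shift_sd_mels Between-participant distribution of
#'   the applied F1 shift magnitude (constant within a participant).
#' @param baseline_f1_mels Population mean F1 of the vowel steady state.
#' @param baseline_participant_sd_mels,baseline_word_sd_mels Between-participant
#'   and between-word SD of the steady-state F1 target.
#' @param onset_offset_mels F1 at vowel onset relative to the steady state
#'   (negative: F1 rises out of the consonant transition).
#' @param transition_tau_ms Time constant of the exponential onset transition.
#' @param noise_trial_sd_mels SD of the per-trial constant F1 offset.
#' @param noise_sample_sd_mels Marginal SD of the smooth within-trial noise.
#' @param noise_smooth_ms Width of the moving average applied to the
#'   within-trial noise.
#' @param comp_gain_mean,comp_gain_sd Mean and between-participant SD of the
#'   compensation gain.
#' @param adapt_gain_mean,adapt_gain_sd Mean and between-participant SD of
#'   the one-shot adaptation gain.
#' @param gain_correlation Correlation between the two gains across
#'   participants.
#' @param comp_latency_ms,comp_rise_ms Compensation onset latency and linear
#'   rise time.
#' @param duration_meanlog,duration_sdlog Log-normal parameters of the vowel
#'   duration (ms); draws are clipped to `[100, 400]` ms.
#' @param short_vowel_frac Fraction of trials given a sub-100 ms vowel
#'   (uniform on `short_vowel_range_ms`) to exercise the duration filter.
#' @param short_vowel_range_ms Range of the short-vowel durations.
#' @param min_post_up,min_post_down,min_baseline_adapt Minimum counts of
#'   post-up, post-down, and baseline (unperturbed-after-unperturbed) trials
#'   a schedule must contain; `NULL` asks for 1 of each where feasible.
#' @param step_ms Trajectory sampling step.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_participants = 20,
                       n_studies = 1,
                       words = c("bed", "dead", "head"),
                       n_trials = 120,
                       p_perturbed = 0.5,
                       shift_mean_mels = 125,
                       shift_sd_mels = 0,
                       baseline_f1_mels = 740,
                       baseline_participant_sd_mels = 45,
                       baseline_word_sd_mels = 15,
                       onset_offset_mels = -80,
                       transition_tau_ms = 30,
                       noise_trial_sd_mels = 30,
                       noise_sample_sd_mels = 20,
                       noise_smooth_ms = 25,
                       comp_gain_mean = 0.05,
                       comp_gain_sd = 0.08,
                       adapt_gain_mean = 0.015,
                       adapt_gain_sd = 0.04,
                       gain_correlation = 0.4,
                       comp_latency_ms = 120,
                       comp_rise_ms = 80,
                       duration_meanlog = log(220),
                       duration_sdlog = 0.25,
                       short_vowel_frac = 0.01,
                       short_vowel_range_ms = c(60, 99),
                       min_post_up = NULL,
                       min_post_down = NULL,
                       min_baseline_adapt = NULL,
                       step_ms = 5,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    n_participants >= 1, n_studies >= 1, n_trials >= 1,
    length(words) >= 1, step_ms > 0
  )
  if (p_perturbed < 0 || p_perturbed > 1) abort("`p_perturbed` must be in [0, 1].")
  sds <- c(
    shift_sd_mels, baseline_participant_sd_mels, baseline_word_sd_mels,
    noise_trial_sd_mels, noise_sample_sd_mels, comp_gain_sd, adapt_gain_sd
  )
  if (any(sds < 0)) abort("All SD parameters must be >= 0.")
  if (abs(gain_correlation) > 1) abort("`gain_correlation` must be in [-1, 1].")
  if (short_vowel_frac < 0 || short_vowel_frac > 1) {
    abort("`short_vowel_frac` must be in [0, 1].")
  }
  counts <- schedule_counts(n_trials, p_perturbed)
  auto_min <- function(x, feasible) {
    if (!is.null(x)) return(as.integer(x))
    if (feasible) 1L else 0L
  }
  n_unpert <- n_trials - counts$n_pert
  cfg$min_post_up <- auto_min(min_post_up, counts$n_up > 0 && n_unpert > 0)
  cfg$min_post_down <- auto_min(min_post_down, counts$n_down > 0 && n_unpert > 0)
  cfg$min_baseline_adapt <- auto_min(min_baseline_adapt, n_unpert >= 2)
  check_schedule_feasible(cfg)
  structure(cfg, class = "sim_config")
}

schedule_counts <- function(n_trials, p_perturbed) {
  n_pert <- round(p_perturbed * n_trials)
  n_up <- ceiling(n_pert / 2)
  list(n_pert = n_pert, n_up = n_up, n_down = n_pert - n_up)
}

check_schedule_feasible <- function(cfg) {
  counts <- schedule_counts(cfg$n_trials, cfg$p_perturbed)
  n_unpert <- cfg$n_trials - counts$n_pert
  # an unperturbed trial can follow at most one perturbed trial, and vice versa
  max_post_up <- min(counts$n_up, n_unpert)
  max_post_down <- min(counts$n_down, n_unpert)
  max_posts <- min(counts$n_pert, n_unpert)
  max_base <- max(n_unpert - counts$n_pert, n_unpert - 1, 0)
  ok <- cfg$min_post_up <= max_post_up &&
    cfg$min_post_down <= max_post_down &&
    cfg$min_post_up + cfg$min_post_down <= max_posts &&
    cfg$min_baseline_adapt <= max_base
  if (!ok) {
    abort(paste0(
      "Infeasible schedule constraints: n_trials=", cfg$n_trials,
      ", p_perturbed=", cfg$p_perturbed,
      " cannot supply min_post_up=", cfg$min_post_up,
      ", min_post_down=", cfg$min_post_down,
      ", min_baseline_adapt=", cfg$min_baseline_adapt
    ))
  }
  invisible(cfg)
}

#' Generate one session's trial schedule
#'
#' Draws a pseudorandom trial sequence: `round(p_perturbed * n_trials)`
#' perturbed trials with up and down shifts balanced to within one, the rest
#' unperturbed, permuted uniformly and re-drawn until the schedule contains
#' the configured minimum numbers of post-up, post-down, and
#' unperturbed-after-unperturbed trials. Words cycle over shuffled blocks of
#' the word list so that every word recurs throughout the session.
#'
#' Uses the current RNG state; seed management belongs to the caller
#' ([simulate_experiment()] seeds a named substream).
#'
#' @param cfg A [sim_config()].
#' @param magnitude_mels Shift magnitude applied on this session's perturbed
#'   trials (participant-specific in several of the emulated studies).
#' @return A tibble with `trial_index`, `word`, `perturbation`,
#'   `shift_magnitude_mels`.
#' @export
generate_schedule <- function(cfg, magnitude_mels = cfg$shift_mean_mels) {
  check_schedule_feasible(cfg)
  counts <- schedule_counts(cfg$n_trials, cfg$p_perturbed)
  base <- c(
    rep("up", counts$n_up), rep("down", counts$n_down),
    rep("none", cfg$n_trials - counts$n_pert)
  )
  for (attempt in seq_len(1000)) {
    pert <- sample(base)
    prev <- c(NA_character_, pert[-cfg$n_trials])
    is_post_up <- pert == "none" & !is.na(prev) & prev == "up"
    is_post_down <- pert == "none" & !is.na(prev) & prev == "down"
    is_base_adapt <- pert == "none" & !is.na(prev) & prev == "none"
    if (sum(is_post_up) >= cfg$min_post_up &&
        sum(is_post_down) >= cfg$min_post_down &&
        sum(is_base_adapt) >= cfg$min_baseline_adapt) {
      words <- as.vector(replicate(
        ceiling(cfg$n_trials / length(cfg$words)),
        sample(cfg$words)
      ))[seq_len(cfg$n_trials)]
      return(tibble::tibble(
        trial_index = seq_len(cfg$n_trials),
        word = words,
        perturbation = pert,
        shift_magnitude_mels = ifelse(pert == "none", 0, magnitude_mels)
      ))
    }
  }
  abort("Could not draw a schedule meeting the minimum role counts in 1000 attempts.")
}

ramp_fraction <- function(t_ms, latency_ms, rise_ms) {
  if (rise_ms <= 0) return(as.numeric(t_ms >= latency_ms))
  pmin(1, pmax(0, (t_ms - latency_ms) / rise_ms))
}

pert_sign <- function(perturbation) {
  ifelse(perturbation == "up", 1, ifelse(perturbation == "down", -1, 0))
}

#' Generate a single trial trajectory from the behavioral model
#'
#' Scalar reference implementation of the generative model: the trajectory is
#' the word baseline \eqn{b_w(t) = target + onset\_offset \cdot e^{-t/\tau}}
#' plus, on perturbed trials, a compensation component
#' \eqn{c(t) = -sign(shift) \cdot g_c \cdot |shift| \cdot ramp(t)} rising
#' linearly between `comp_latency_ms` and `comp_latency_ms + comp_rise_ms`,
#' plus, on trials directly following a perturbed trial, a constant one-shot
#' adaptation offset \eqn{a = -sign(prev) \cdot g_a \cdot |prev|}, plus a
#' per-trial offset and smooth within-trial noise. [simulate_experiment()]
#' evaluates the same model vectorized.
#'
#' @param cfg A [sim_config()] (supplies the kinematic and noise constants).
#' @param word_target_mels Steady-state F1 target of this word for this
#'   participant.
#' @param comp_gain,adapt_gain This participant's gains.
#' @param perturbation `"none"`, `"up"`, or `"down"` for this trial.
#' @param magnitude_mels Shift magnitude on this trial (0 if unperturbed).
#' @param prev_perturbation,prev_magnitude_mels Perturbation of the directly
#'   preceding trial (`NA`/`"none"` and 0 if none).
#' @param duration_ms Vowel duration; the trajectory has
#'   `floor(duration_ms / step_ms) + 1` samples.
#' @param noise If `FALSE`, return the deterministic part only.
#' @return A list with `f1` (the trajectory), `comp_amplitude_mels` (signed
#'   plateau of the compensation component) and `adapt_offset_mels` (signed
#'   adaptation offset).
#' @export
generate_trial <- function(cfg, word_target_mels, comp_gain, adapt_gain,
                           perturbation, magnitude_mels,
                           prev_perturbation, prev_magnitude_mels,
                           duration_ms, noise = TRUE) {
  n <- floor(duration_ms / cfg$step_ms) + 1
  t_ms <- (seq_len(n) - 1) * cfg$step_ms
  b <- word_target_mels + cfg$onset_offset_mels * exp(-t_ms / cfg$transition_tau_ms)
  comp_amp <- -pert_sign(perturbation) * comp_gain * magnitude_mels
  adapt_off <- if (!is.na(prev_perturbation) && prev_perturbation != "none") {
    -pert_sign(prev_perturbation) * adapt_gain * prev_magnitude_mels
  } else {
    0
  }
  f1 <- b + comp_amp * ramp_fraction(t_ms, cfg$comp_latency_ms, cfg$comp_rise_ms) +
    adapt_off
  if (noise) {
    f1 <- f1 + rnorm(1, 0, cfg$noise_trial_sd_mels) +
      smooth_noise(n, cfg$noise_sample_sd_mels, cfg$noise_smooth_ms, cfg$step_ms)
  }
  list(f1 = f1, comp_amplitude_mels = comp_amp, adapt_offset_mels = adapt_off)
}

# Moving-average-smoothed Gaussian noise with the requested marginal SD.
smooth_noise <- function(n, sd_mels, smooth_ms, step_ms) {
  if (sd_mels == 0) return(numeric(n))
  k <- max(1L, round(smooth_ms / step_ms))
  if (k == 1L) return(rnorm(n, 0, sd_mels))
  w <- rnorm(n + k - 1, 0, sd_mels * sqrt(k))
  as.numeric(stats::filter(w, rep(1 / k, k), sides = 1))[k:(n + k - 1)]
}

# Same smoothing applied column-wise to a (time x trial) noise matrix.
smooth_noise_matrix <- function(n_time, n_trials, sd_mels, smooth_ms, step_ms) {
  if (sd_mels == 0) return(matrix(0, n_time, n_trials))
  k <- max(1L, round(smooth_ms / step_ms))
  if (k == 1L) return(matrix(rnorm(n_time * n_trials, 0, sd_mels), n_time, n_trials))
  w <- matrix(rnorm((n_time + k - 1) * n_trials, 0, sd_mels * sqrt(k)),
              n_time + k - 1, n_trials)
  sm <- stats::filter(w, rep(1 / k, k), sides = 1)
  matrix(sm[k:(n_time + k - 1), ], n_time, n_trials)
}

substream_seed <- function(seed, name) {
  (as.integer(seed) %% 1000003L) * 2011L +
    sum(utf8ToInt(name) * seq_along(utf8ToInt(name))) %% 1000003L
}

#' Simulate a complete multi-study experiment
#'
#' Draws participants (gains, baseline targets, shift magnitudes), a trial
#' schedule per session, vowel durations, and per-trial F1 trajectories from
#' the generative model of [generate_trial()], fully deterministically given
#' `cfg$seed`. Per-participant (compensation gain, adaptation gain) pairs are
#' bivariate normal with correlation `cfg$gain_correlation`. A fraction
#' `cfg$short_vowel_frac` of vowels is shorter than 100 ms so the duration
#' filter has work to do.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `"sim_experiment"` with elements
#'   \describe{
#'     \item{trials}{a trial table ([as_trial_table()]).}
#'     \item{truth}{ground truth: `$participants` (gains, magnitudes, word
#'       targets) and `$trials` (signed injected compensation amplitude and
#'       adaptation offset per trial).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed), add = TRUE)

  set.seed(substream_seed(cfg$seed, "participants"))
  n_ppt <- cfg$n_participants * cfg$n_studies
  z1 <- rnorm(n_ppt)
  z2 <- rnorm(n_ppt)
  rho <- cfg$gain_correlation
  participants <- tibble::tibble(
    study_id = rep(sprintf("study%02d", seq_len(cfg$n_studies)),
                   each = cfg$n_participants),
    participant_id = rep(sprintf("p%03d", seq_len(cfg$n_participants)),
                         times = cfg$n_studies),
    comp_gain = cfg$comp_gain_mean + cfg$comp_gain_sd * z1,
    adapt_gain = cfg$adapt_gain_mean +
      cfg$adapt_gain_sd * (rho * z1 + sqrt(1 - rho^2) * z2),
    shift_magnitude_mels = draw_positive(
      n_ppt, cfg$shift_mean_mels, cfg$shift_sd_mels
    ),
    baseline_target_mels = rnorm(
      n_ppt, cfg$baseline_f1_mels, cfg$baseline_participant_sd_mels
    )
  )
  word_targets <- tidyr::expand_grid(
    participants[, c("study_id", "participant_id", "baseline_target_mels")],
    word = cfg$words
  )
  word_targets$target_mels <- word_targets$baseline_target_mels +
    rnorm(nrow(word_targets), 0, cfg$baseline_word_sd_mels)
  word_targets$baseline_target_mels <- NULL

  set.seed(substream_seed(cfg$seed, "schedule"))
  sessions <- vector("list", n_ppt)
  for (i in seq_len(n_ppt)) {
    sched <- generate_schedule(cfg, participants$shift_magnitude_mels[i])
    sched$study_id <- participants$study_id[i]
    sched$participant_id <- participants$participant_id[i]
    sessions[[i]] <- sched
  }
  trials <- dplyr::bind_rows(sessions)

  set.seed(substream_seed(cfg$seed, "durations"))
  n_tr <- nrow(trials)
  dur <- pmin(400, pmax(100, rlnorm(n_tr, cfg$duration_meanlog, cfg$duration_sdlog)))
  short <- runif(n_tr) < cfg$short_vowel_frac
  dur[short] <- runif(
    sum(short), cfg$short_vowel_range_ms[1], cfg$short_vowel_range_ms[2]
  )
  trials$vowel_duration_ms <- dur

  # deterministic per-trial model components
  trials <- trials |>
    dplyr::left_join(
      participants[, c("study_id", "participant_id", "comp_gain", "adapt_gain")],
      by = c("study_id", "participant_id")
    ) |>
    dplyr::left_join(
      word_targets, by = c("study_id", "participant_id", "word")
    ) |>
    dplyr::group_by(.data$study_id, .data$participant_id) |>
    dplyr::mutate(
      prev_perturbation = dplyr::lag(.data$perturbation),
      prev_magnitude = dplyr::lag(.data$shift_magnitude_mels)
    ) |>
    dplyr::ungroup()
  comp_amp <- -pert_sign(trials$perturbation) * trials$comp_gain *
    trials$shift_magnitude_mels
  post <- !is.na(trials$prev_perturbation) & trials$prev_perturbation != "none"
  adapt_off <- ifelse(
    post,
    -pert_sign(trials$prev_perturbation) * trials$adapt_gain *
      dplyr::coalesce(trials$prev_magnitude, 0),
    0
  )

  set.seed(substream_seed(cfg$seed, "noise"))
  n_samp <- floor(trials$vowel_duration_ms / cfg$step_ms) + 1
  max_len <- max(n_samp)
  t_ms <- (seq_len(max_len) - 1) * cfg$step_ms
  # time x trial matrix of the full model
  base_mat <- outer(exp(-t_ms / cfg$transition_tau_ms), rep(1, n_tr)) *
    cfg$onset_offset_mels +
    matrix(trials$target_mels, max_len, n_tr, byrow = TRUE)
  comp_mat <- outer(
    ramp_fraction(t_ms, cfg$comp_latency_ms, cfg$comp_rise_ms), comp_amp
  )
  trial_off <- rnorm(n_tr, 0, cfg$noise_trial_sd_mels)
  noise_mat <- smooth_noise_matrix(
    max_len, n_tr, cfg$noise_sample_sd_mels, cfg$noise_smooth_ms, cfg$step_ms
  )
  f1_mat <- base_mat + comp_mat + noise_mat +
    matrix(adapt_off + trial_off, max_len, n_tr, byrow = TRUE)
  f1 <- lapply(seq_len(n_tr), function(i) f1_mat[seq_len(n_samp[i]), i])

  out <- trials
  out$f1 <- f1
  out$step_ms <- cfg$step_ms
  out <- as_trial_table(out[, c(
    "study_id", "participant_id", "trial_index", "word", "perturbation",
    "shift_magnitude_mels", "vowel_duration_ms", "step_ms", "f1"
  )])
  truth_trials <- tibble::tibble(
    study_id = trials$study_id,
    participant_id = trials$participant_id,
    trial_index = trials$trial_index,
    comp_amplitude_mels = comp_amp,
    adapt_offset_mels = adapt_off,
    trial_offset_mels = trial_off
  )
  structure(
    list(
      trials = out,
      truth = list(
        participants = participants,
        word_targets = word_targets,
        trials = truth_trials
      ),
      config = cfg
    ),
    class = "sim_experiment"
  )
}

draw_positive <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  while (any(x <= 0)) x[x <= 0] <- rnorm(sum(x <= 0), mean, sd)
  x
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}
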