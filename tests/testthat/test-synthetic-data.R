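test_that("schedules have the configured perturbed fraction and direction balance", {
  cfg <- sim_config(n_trials = 120, p_perturbed = 0.5)
  set.seed(11)
  sched <- generate_schedule(cfg)
  expect_equal(sum(sched$perturbation != "none"), 60)
  expect_lte(abs(sum(sched$perturbation == "up") - sum(sched$perturbation == "down")), 1)
  expect_equal(nrow(sched), 120)
  # every word recurs
  expect_setequal(unique(sched$word), cfg$words)
  # magnitudes attach only to perturbed trials
  expect_true(all((sched$shift_magnitude_mels > 0) == (sched$perturbation != "none")))
})

test_that("a fully unperturbed schedule makes every later trial a baseline trial", {
  cfg <- sim_config(n_trials = 30, p_perturbed = 0, n_participants = 1)
  trials <- simulate_experiment(cfg)$trials
  lab <- label_trials(trials)
  expect_true(all(lab$perturbation == "none"))
  expect_equal(sum(lab$post_up | lab$post_down), 0)
  expect_equal(which(lab$baseline_adapt), 2:30)
})

test_that("perturbed fraction is calibrated across many schedule draws", {
  cfg <- sim_config(n_trials = 120, p_perturbed = 1 / 3)
  set.seed(202)
  fractions <- replicate(1000, {
    mean(generate_schedule(cfg)$perturbation != "none")
  })
  expect_equal(mean(fractions), 1 / 3, tolerance = 0.01)
})

test_that("infeasible schedule constraints are a config error", {
  expect_error(
    sim_config(p_perturbed = 1, min_post_up = 1),
    "Infeasible schedule"
  )
  expect_error(
    sim_config(n_trials = 10, p_perturbed = 0, min_baseline_adapt = 50),
    "Infeasible schedule"
  )
  # p = 1 is fine when no post-perturbation trials are demanded
  expect_s3_class(sim_config(p_perturbed = 1), "sim_config")
})

test_that("the trial model produces the documented deterministic components", {
  cfg <- quiet_sim()
  t_ms <- seq(0, 300, by = cfg$step_ms)
  b <- 740 + cfg$onset_offset_mels * exp(-t_ms / cfg$transition_tau_ms)

  # null effects reproduce the word baseline exactly
  tr <- generate_trial(
    cfg, 740, comp_gain = 0, adapt_gain = 0,
    perturbation = "none", magnitude_mels = 0,
    prev_perturbation = "none", prev_magnitude_mels = 0,
    duration_ms = 300, noise = FALSE
  )
  expect_equal(tr$f1, b)
  expect_equal(tr$comp_amplitude_mels, 0)
  expect_equal(tr$adapt_offset_mels, 0)

  # upward shift with positive gain pushes F1 down only after the latency
  tr <- generate_trial(
    cfg, 740, comp_gain = 0.05, adapt_gain = 0,
    perturbation = "up", magnitude_mels = 125,
    prev_perturbation = "none", prev_magnitude_mels = 0,
    duration_ms = 300, noise = FALSE
  )
  pre <- t_ms <= cfg$comp_latency_ms
  expect_equal(tr$f1[pre], b[pre])
  expect_true(all(tr$f1[!pre] < b[!pre]))
  expect_equal(min(tr$f1 - b), -0.05 * 125)

  # one trial after a downward shift: constant positive offset from onset
  tr <- generate_trial(
    cfg, 740, comp_gain = 0, adapt_gain = 0.02,
    perturbation = "none", magnitude_mels = 0,
    prev_perturbation = "down", prev_magnitude_mels = 125,
    duration_ms = 300, noise = FALSE
  )
  expect_equal(tr$f1 - b, rep(2.5, length(b)))
})

test_that("the vectorized experiment generator agrees with the scalar model", {
  cfg <- quiet_sim(n_participants = 2, n_trials = 30, seed = 5)
  exp_out <- simulate_experiment(cfg)
  lab <- label_trials(exp_out$trials)
  truth <- exp_out$truth
  for (i in sample(nrow(lab), 10)) {
    row <- lab[i, ]
    target <- truth$word_targets$target_mels[
      truth$word_targets$participant_id == row$participant_id &
        truth$word_targets$word == row$word
    ]
    ref <- generate_trial(
      cfg, target, comp_gain = cfg$comp_gain_mean, adapt_gain = cfg$adapt_gain_mean,
      perturbation = row$perturbation,
      magnitude_mels = row$shift_magnitude_mels,
      prev_perturbation = row$prev_perturbation,
      prev_magnitude_mels = row$prev_shift_magnitude_mels %||% 0,
      duration_ms = row$vowel_duration_ms, noise = FALSE
    )
    expect_equal(row$f1[[1]], ref$f1, tolerance = 1e-12)
  }
})

test_that("experiments are deterministic given the seed and structurally valid", {
  cfg <- sim_config(n_participants = 2, n_trials = 20, seed = 99)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$trials, b$trials)
  expect_identical(a$truth, b$truth)
  expect_equal(nrow(a$trials), 40)
  expect_silent(validate_trials(a$trials))
  # ground truth covers every participant and trial
  expect_equal(nrow(a$truth$participants), 2)
  expect_equal(nrow(a$truth$trials), 40)
  # different seeds give different data
  expect_false(identical(
    a$trials$f1, simulate_experiment(sim_config(
      n_participants = 2, n_trials = 20, seed = 100
    ))$trials$f1
  ))
})

test_that("participant gain pairs realize the configured correlation", {
  cfg <- sim_config(
    n_participants = 500, n_trials = 2, p_perturbed = 0.5,
    gain_correlation = 0.6, seed = 3,
    min_post_up = 0, min_post_down = 0, min_baseline_adapt = 0
  )
  ppt <- simulate_experiment(cfg)$truth$participants
  expect_lt(abs(cor(ppt$comp_gain, ppt$adapt_gain) - 0.6), 0.1)
  expect_lt(abs(mean(ppt$comp_gain) - cfg$comp_gain_mean),
            3 * cfg$comp_gain_sd / sqrt(500))
  expect_lt(abs(mean(ppt$adapt_gain) - cfg$adapt_gain_mean),
            3 * cfg$adapt_gain_sd / sqrt(500))
})

test_that("short vowels appear at the configured rate", {
  cfg <- sim_config(
    n_participants = 20, n_trials = 120, short_vowel_frac = 0.01, seed = 8
  )
  trials <- simulate_experiment(cfg)$trials
  expect_lt(abs(mean(trials$vowel_duration_ms < 100) - 0.01), 0.006)
})

test_that("null-effect simulations give responses centered on zero", {
  # all gains zero: one-sample t on the participant-mean responses should be
  # non-significant in the vast majority of repeated experiments
  p_comp <- numeric(30)
  p_adapt <- numeric(30)
  for (k in seq_len(30)) {
    cfg <- sim_config(
      n_participants = 10, n_trials = 60,
      comp_gain_mean = 0, comp_gain_sd = 0,
      adapt_gain_mean = 0, adapt_gain_sd = 0,
      short_vowel_frac = 0, seed = 5000 + k
    )
    res <- quick_responses(simulate_experiment(cfg)$trials)
    comp_means <- tapply(
      sign_correct(res$comp_ppt)$value_mels, res$comp_ppt$participant_id,
      mean, na.rm = TRUE
    )
    adapt_means <- tapply(
      sign_correct(res$adapt_ppt)$value_mels, res$adapt_ppt$participant_id,
      mean, na.rm = TRUE
    )
    p_comp[k] <- t.test(comp_means)$p.value
    p_adapt[k] <- t.test(adapt_means)$p.value
  }
  expect_gte(mean(p_comp > 0.05), 0.9)
  expect_gte(mean(p_adapt > 0.05), 0.9)
})
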