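test_that("window means use half-open windows and a coverage rule", {
  traj <- rep(3, 61) # 300 ms at 5 ms step
  expect_equal(window_mean(traj, 5, 150, 250), 3)
  expect_equal(window_mean(traj, 5, 0, 100), 3)
  expect_error(window_mean(traj, 5, 100, 100), "t0_ms")

  # trajectory ending at 200 ms: window [150, 250) half-covered
  short <- c(rep(0, 30), seq_len(11)) # samples at 0..200 ms
  expect_equal(
    window_mean(short, 5, 150, 250, min_coverage = 0.4),
    mean(short[31:41]) # samples at 150..200 ms
  )
  expect_true(is.na(window_mean(short, 5, 150, 250, min_coverage = 0.6)))
  # the sample at exactly t1 is excluded (half-open)
  expect_equal(window_mean(short, 5, 150, 200, min_coverage = 1), mean(short[31:40]))
})

test_that("window means equal brute-force averages on random fixtures", {
  set.seed(9)
  for (i in 1:25) {
    step <- sample(c(2, 4, 5, 10), 1)
    n <- sample(20:90, 1)
    traj <- rnorm(n)
    t0 <- sample(0:150, 1)
    t1 <- t0 + sample(c(50, 100, 120), 1)
    got <- window_mean(traj, step, t0, t1, min_coverage = 0)
    t_all <- (seq_len(n) - 1) * step
    sel <- t_all >= t0 & t_all < t1
    expected <- if (any(sel)) mean(traj[sel]) else NA_real_
    expect_equal(got, expected)
  }
})

test_that("trial compensation matches the closed-form ramp integral", {
  cfg <- quiet_sim(
    n_participants = 1, n_trials = 60, seed = 13, adapt_gain_mean = 0,
    duration_meanlog = log(300), duration_sdlog = 0
  )
  res <- quick_responses(simulate_experiment(cfg)$trials)
  # noise-free: every up trial equals -gain * shift * mean(ramp over window)
  t_win <- seq(150, 245, by = 5)
  ramp <- pmin(1, pmax(0, (t_win - cfg$comp_latency_ms) / cfg$comp_rise_ms))
  expected <- -cfg$comp_gain_mean * cfg$shift_mean_mels * mean(ramp)
  up <- res$comp_trial[res$comp_trial$direction == "up", ]
  down <- res$comp_trial[res$comp_trial$direction == "down", ]
  expect_true(all(abs(up$value_mels - expected) < 1e-9))
  # direction antisymmetry: down trials mirror up trials exactly
  expect_true(all(abs(down$value_mels + expected) < 1e-9))
})

test_that("trial adaptation is the constant-offset previous-shift response", {
  cfg <- quiet_sim(
    n_participants = 1, n_trials = 60,
    adapt_gain_mean = 0.02, seed = 17
  )
  res <- quick_responses(simulate_experiment(cfg)$trials)
  post_down <- res$adapt_trial[res$adapt_trial$direction == "down", ]
  expect_true(all(abs(post_down$value_mels - 0.02 * 125) < 1e-9))
  post_up <- res$adapt_trial[res$adapt_trial$direction == "up", ]
  expect_true(all(abs(post_up$value_mels + 0.02 * 125) < 1e-9))
  # direction is inherited from the preceding trial, with its index recorded
  expect_true(all(post_up$prev_trial_index == post_up$trial_index - 1L))

  # a constant offset is insensitive to the window choice
  alt <- trial_responses(res$norm_adapt, "adaptation", window = c(50, 150))
  expect_equal(alt$value_mels, res$adapt_trial$value_mels, tolerance = 1e-9)

  # zero-gain trials give zero adaptation
  cfg0 <- quiet_sim(n_participants = 1, n_trials = 60, adapt_gain_mean = 0, seed = 17)
  res0 <- quick_responses(simulate_experiment(cfg0)$trials)
  expect_true(all(abs(res0$adapt_trial$value_mels) < 1e-9))
})

test_that("responses are computed only for trials in the right role", {
  cfg <- quiet_sim(n_participants = 1, n_trials = 40, seed = 2)
  res <- quick_responses(simulate_experiment(cfg)$trials)
  expect_error(
    trial_responses(res$norm_adapt, "compensation"),
    "only for perturbed"
  )
  expect_error(
    trial_responses(res$norm_comp, "adaptation"),
    "only for post-perturbation"
  )
})

test_that("participant averages follow average-then-window order", {
  # single trial: the average is that trial
  expect_equal(participant_average_trajectory(list(c(1, 2, 3))), c(1, 2, 3))
  # mirrored trials cancel
  expect_equal(
    participant_average_trajectory(list(c(2, 4), c(-2, -4))),
    c(0, 0)
  )
  # unequal lengths: pointwise average differs from averaging window means
  norm <- list(rep(2, 41), rep(6, 61)) # 200 and 300 ms
  avg <- participant_average_trajectory(norm)
  expect_equal(avg, c(rep(4, 41), rep(6, 20)))
  atw <- window_mean(avg, 5, 150, 250) # average-then-window
  wta <- mean(c(
    window_mean(norm[[1]], 5, 150, 250, min_coverage = 0.4),
    window_mean(norm[[2]], 5, 150, 250, min_coverage = 0.4)
  ))
  expect_equal(atw, mean(c(rep(4, 11), rep(6, 9))))
  expect_false(isTRUE(all.equal(atw, wta)))
  # with equal-length trials the two orders agree (linearity)
  norm_eq <- list(rnorm(61), rnorm(61))
  avg_eq <- participant_average_trajectory(norm_eq)
  expect_equal(
    window_mean(avg_eq, 5, 150, 250),
    mean(vapply(norm_eq, window_mean, numeric(1), 5, 150, 250))
  )
})

test_that("participant-level responses match brute-force pointwise computation", {
  cfg <- sim_config(n_participants = 3, n_trials = 60, seed = 31)
  res <- quick_responses(simulate_experiment(cfg)$trials)
  got <- res$comp_ppt
  for (i in seq_len(nrow(got))) {
    sel <- res$norm_comp$participant_id == got$participant_id[i] &
      ifelse(res$norm_comp$perturbed_up, "up", "down") == got$direction[i]
    m <- oneshotadapt:::traj_matrix(res$norm_comp$norm[sel])
    avg <- colMeans(m, na.rm = TRUE)
    t_all <- (seq_along(avg) - 1) * 5
    expected <- mean(avg[t_all >= 150 & t_all < 250])
    expect_equal(got$value_mels[i], expected, tolerance = 1e-9)
  }
})

test_that("sign correction negates up responses once and only once", {
  rows <- tibble::tibble(
    direction = c("up", "down"),
    value_mels = c(-3, 2),
    sign_corrected = FALSE
  )
  sc <- sign_correct(rows)
  expect_equal(sc$value_mels, c(3, 2))
  expect_true(all(sc$sign_corrected))
  expect_error(sign_correct(sc), "already sign-corrected")
})

test_that("sign-corrected response means recover the injected gains", {
  # across seeds, mean compensation ~ gain * shift * E[ramp], mean
  # adaptation ~ gain * shift, each within 2 SE of the participant means
  comp_means <- c()
  adapt_means <- c()
  for (seed in 301:305) {
    cfg <- sim_config(n_participants = 12, n_trials = 120, seed = seed,
                      comp_gain_sd = 0.02, adapt_gain_sd = 0.01)
    res <- quick_responses(simulate_experiment(cfg)$trials)
    comp_sc <- sign_correct(res$comp_ppt)
    adapt_sc <- sign_correct(res$adapt_ppt)
    comp_means <- c(comp_means, tapply(
      comp_sc$value_mels, comp_sc$participant_id, mean, na.rm = TRUE
    ))
    adapt_means <- c(adapt_means, tapply(
      adapt_sc$value_mels, adapt_sc$participant_id, mean, na.rm = TRUE
    ))
  }
  t_win <- seq(150, 245, by = 5)
  e_ramp <- mean(pmin(1, pmax(0, (t_win - 120) / 80)))
  expect_lt(
    abs(mean(comp_means) - 0.05 * 125 * e_ramp),
    2 * sd(comp_means) / sqrt(length(comp_means))
  )
  expect_lt(
    abs(mean(adapt_means) - 0.015 * 125),
    2 * sd(adapt_means) / sqrt(length(adapt_means))
  )
})
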