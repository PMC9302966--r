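make_response_rows <- function(values, direction, participant, study = "s1") {
  tibble::tibble(
    study_id = study,
    participant_id = participant,
    trial_index = seq_along(values),
    direction = direction,
    measure = "compensation",
    window_t0_ms = 150, window_t1_ms = 250,
    value_mels = values,
    sign_corrected = FALSE,
    shift_magnitude_mels = 125,
    prev_trial_index = NA_integer_
  )
}

test_that("with one participant the direction model reduces to two-group OLS", {
  set.seed(55)
  n <- 40
  dirs <- rep(c("up", "down"), each = n / 2)
  vals <- ifelse(dirs == "up", -4, 3) + rnorm(n, 0, 2)
  rows <- make_response_rows(vals, dirs, participant = "p1")
  fit <- fit_direction_model(rows)
  expect_setequal(fit$dropped_random, c("participant", "study"))
  expect_equal(fit$method, "lm")

  beta <- fit$terms[fit$terms$term == "directionup", ]
  # closed-form OLS: difference of group means, pooled-variance SE
  mu <- mean(vals[dirs == "up"]) - mean(vals[dirs == "down"])
  s2 <- (sum((vals[dirs == "up"] - mean(vals[dirs == "up"]))^2) +
           sum((vals[dirs == "down"] - mean(vals[dirs == "down"]))^2)) / (n - 2)
  expect_equal(beta$estimate, mu, tolerance = 1e-6)
  expect_equal(beta$se, sqrt(s2 * (2 / (n / 2))), tolerance = 1e-6)
  expect_equal(beta$df, n - 2)
  expect_equal(beta$d, beta$estimate / fit$residual_sd)
  expect_equal(beta$eta_sq_partial, beta$t^2 / (beta$t^2 + beta$df))
})

test_that("the direction coefficient is up minus down in the balanced case", {
  set.seed(66)
  # 6 participants, equal trials per direction, one study
  dat <- expand.grid(participant = sprintf("p%d", 1:6), rep = 1:10,
                     direction = c("down", "up"))
  ppt_eff <- setNames(rnorm(6, 0, 5), sprintf("p%d", 1:6))
  dat$value <- ppt_eff[dat$participant] +
    ifelse(dat$direction == "up", -3.5, 3.5) + rnorm(nrow(dat))
  rows <- make_response_rows(dat$value, as.character(dat$direction),
                             participant = as.character(dat$participant))
  rows$trial_index <- seq_len(nrow(rows))
  fit <- fit_direction_model(rows)
  expect_equal(fit$method, "lmer-REML-Satterthwaite")
  expect_equal(fit$dropped_random, "study")
  beta <- fit$terms$estimate[fit$terms$term == "directionup"]
  expect_equal(
    beta,
    mean(dat$value[dat$direction == "up"]) -
      mean(dat$value[dat$direction == "down"]),
    tolerance = 1e-9
  )
})

test_that("the direction model recovers the simulated direction effect", {
  cfg <- sim_config(n_participants = 15, n_trials = 120, seed = 404,
                    comp_gain_sd = 0.02)
  res <- quick_responses(simulate_experiment(cfg)$trials)
  fit <- fit_direction_model(res$comp_trial)
  t_win <- seq(150, 245, by = 5)
  e_ramp <- mean(pmin(1, pmax(0, (t_win - 120) / 80)))
  truth <- -2 * cfg$comp_gain_mean * cfg$shift_mean_mels * e_ramp
  beta <- fit$terms[fit$terms$term == "directionup", ]
  expect_lt(abs(beta$estimate - truth), 2 * beta$se)
  expect_error(
    fit_direction_model(sign_correct(res$comp_trial)),
    "sign-corrected"
  )
})

test_that("paired and one-sample t-tests match textbook formulas", {
  up <- c(-5.1, -3.2, -6.4, -2.2, -4.8)
  down <- c(2.0, 4.1, 1.2, 3.3, 2.9)
  res <- paired_and_one_sample_tests(up, down)

  d <- up - down
  t_paired <- mean(d) / (sd(d) / sqrt(5))
  row <- res[res$test == "paired_up_vs_down", ]
  expect_equal(row$t, t_paired)
  expect_equal(row$df, 4)
  expect_equal(row$p, 2 * pt(-abs(t_paired), 4))
  expect_equal(row$cohen_d, mean(d) / sd(d))

  row_up <- res[res$test == "one_sample_up", ]
  expect_equal(row_up$t, mean(up) / (sd(up) / sqrt(5)))
  expect_equal(row_up$cohen_d, mean(up) / sd(up))
  expect_lt(row$t, 0)

  # degenerate all-equal input is reported as undefined, not an error
  res0 <- paired_and_one_sample_tests(rep(0, 5), rep(0, 5))
  expect_true(all(is.na(res0$t)))
  expect_match(res0$note[1], "zero variance")
  expect_error(paired_and_one_sample_tests(1, 1), "at least 2")
})

test_that("relationship model recovers a linear compensation effect", {
  set.seed(77)
  n_ppt <- 40
  pairs <- tidyr::expand_grid(
    study_id = "s1",
    participant_id = sprintf("p%02d", seq_len(n_ppt)),
    rep = 1:20
  )
  pairs$compensation <- rnorm(nrow(pairs), 4, 6)
  pairs$adaptation <- 0.2 * pairs$compensation + rnorm(nrow(pairs), 0, 2)
  pairs$magnitude_mels <- 125
  pairs$direction <- sample(c("up", "down"), nrow(pairs), replace = TRUE)

  fit <- fit_relationship_model(pairs)
  beta <- fit$terms[fit$terms$term == "compensation", ]
  expect_lt(abs(beta$estimate - 0.2), 2 * beta$se)
  # single magnitude: magnitude terms are dropped as unidentifiable
  expect_match(fit$note, "magnitude terms dropped")
  expect_false(any(grepl("magnitude", fit$terms$term)))

  # zero adaptation everywhere: all coefficients near zero
  pairs$adaptation <- rnorm(nrow(pairs), 0, 0.5)
  fit0 <- fit_relationship_model(pairs)
  expect_lt(abs(fit0$terms$estimate[fit0$terms$term == "compensation"]), 0.05)

  # varying magnitudes keep the full model, with mean normalized magnitude 1
  pairs$magnitude_mels <- sample(c(94, 108, 125), nrow(pairs), replace = TRUE)
  pairs$adaptation <- 0.2 * pairs$compensation + rnorm(nrow(pairs), 0, 2)
  fit2 <- fit_relationship_model(pairs)
  expect_true(any(fit2$terms$term == "magnitude_norm"))
  expect_true(any(fit2$terms$term == "compensation:magnitude_norm"))
  expect_equal(mean(pairs$magnitude_mels / mean(pairs$magnitude_mels)), 1)
})

test_that("relationship machinery refuses raw (non-sign-corrected) responses", {
  rows <- make_response_rows(rnorm(10), rep(c("up", "down"), 5), "p1")
  expect_error(pair_responses(rows, rows, level = "trial"), "sign-corrected")
})

test_that("trial pairs join each post trial to its preceding perturbed trial", {
  cfg <- quiet_sim(n_participants = 2, n_trials = 40, seed = 12)
  res <- quick_responses(simulate_experiment(cfg)$trials)
  pairs <- pair_responses(
    sign_correct(res$comp_trial), sign_correct(res$adapt_trial),
    level = "trial"
  )
  expect_true(all(pairs$prev_trial_index == pairs$adapt_trial_index - 1L))
  # noise-free: every pair carries the exact injected (sign-corrected) values
  t_win <- seq(150, 245, by = 5)
  e_ramp <- mean(pmin(1, pmax(0, (t_win - 120) / 80)))
  ok <- !is.na(pairs$compensation)
  expect_true(all(abs(pairs$adaptation - 0.015 * 125) < 1e-9))
  expect_true(all(pairs$compensation[ok] > 0))
})

test_that("Fisher pooling is exact for constant r and flags degenerate r", {
  base <- tidyr::expand_grid(
    study_id = "s1",
    participant_id = sprintf("p%02d", 1:12),
    rep = 1:30
  )
  # construct pairs with identical within-participant correlation
  set.seed(88)
  r_target <- 0.5
  base <- dplyr::group_by(base, participant_id) |>
    dplyr::mutate(
      compensation = {
        x <- scale(rnorm(dplyr::n()))[, 1]
        x
      }
    ) |>
    dplyr::ungroup()
  base <- dplyr::group_by(base, participant_id) |>
    dplyr::mutate(
      adaptation = {
        y <- rnorm(dplyr::n())
        y_perp <- scale(stats::resid(lm(y ~ compensation)))[, 1]
        r_target * compensation + sqrt(1 - r_target^2) * y_perp
      }
    ) |>
    dplyr::ungroup()
  res <- per_participant_correlation(base, min_pairs = 10)
  expect_equal(res$per_participant$r, rep(r_target, 12), tolerance = 1e-9)
  expect_equal(res$mean_r, r_target, tolerance = 1e-9)
  expect_equal(res$n_positive, 12)

  # perfectly linear pairs are clamped with a warning
  lin <- base
  lin$adaptation <- 2 * lin$compensation
  expect_warning(res_lin <- per_participant_correlation(lin, 10), "clamped")
  expect_true(all(res_lin$per_participant$r < 1))
  expect_true(all(res_lin$per_participant$r > 1 - 1e-9))
})

test_that("independent trial noise gives per-participant r centered on zero", {
  set.seed(99)
  n_ppt <- 200
  pairs <- tidyr::expand_grid(
    study_id = "s1",
    participant_id = sprintf("p%03d", seq_len(n_ppt)),
    rep = 1:40
  )
  pairs$compensation <- rnorm(nrow(pairs))
  pairs$adaptation <- rnorm(nrow(pairs))
  res <- per_participant_correlation(pairs, min_pairs = 10)
  expect_equal(res$n_participants, n_ppt)
  expect_lt(abs(res$mean_r), 0.05)
  expect_gt(res$p, 0.01)
})
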