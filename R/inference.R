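#' Mixed-effects model for the effect of perturbation direction
#'
#' Fits the trial-level direction model for one measure:
#' `value ~ direction + (1 | participant) + (1 | study)`, with treatment
#' coding and `down` as the reference level so that the direction coefficient
#' is the up-minus-down difference. Estimation is REML; p-values use
#' Satterthwaite degrees of freedom (lmerTest). A random-intercept term whose
#' grouping factor has fewer than two levels cannot be estimated and is
#' dropped (recorded in the result); with no usable random term the model
#' reduces to ordinary least squares.
#'
#' Per-term effect size `d` is the coefficient divided by the residual
#' standard deviation, and `eta_sq_partial` is `t^2 / (t^2 + df)`.
#'
#' @param rows A trial-level response table for one measure (raw, not
#'   sign-corrected: the direction contrast is the quantity of interest).
#' @return A list of class `"adapt_model"`: `terms` (tibble of estimate, SE,
#'   df, t, p, d, eta_sq_partial), `residual_sd`, `singular`,
#'   `dropped_random`, `method`, `n`, and the fitted model object.
#' @export
fit_direction_model <- function(rows) {
  rows <- rows[!is.na(rows$value_mels), , drop = FALSE]
  if (length(unique(rows$direction)) < 2) {
    abort("Both directions are needed to estimate a direction effect.")
  }
  if (any(rows$sign_corrected)) {
    abort("The direction model takes raw (not sign-corrected) responses.")
  }
  dat <- data.frame(
    value = rows$value_mels,
    direction = factor(rows$direction, levels = c("down", "up")),
    participant = interaction(rows$study_id, rows$participant_id, drop = TRUE),
    study = factor(rows$study_id)
  )
  fit_lmm(value ~ direction, dat, random = c("participant", "study"))
}

# Shared fitting path: lmer with Satterthwaite df where random terms are
# usable, lm otherwise.
fit_lmm <- function(fixed_formula, dat, random) {
  usable <- random[vapply(random, function(g) nlevels(dat[[g]]) >= 2, logical(1))]
  dropped <- setdiff(random, usable)
  if (length(usable) > 0) {
    rhs <- paste(
      c(as.character(fixed_formula)[3],
        paste0("(1 | ", usable, ")")),
      collapse = " + "
    )
    form <- as.formula(paste(as.character(fixed_formula)[2], "~", rhs))
    fit <- lmerTest::lmer(form, data = dat, REML = TRUE)
    smry <- coef(summary(fit))
    singular <- lme4::isSingular(fit)
    method <- "lmer-REML-Satterthwaite"
  } else {
    fit <- lm(fixed_formula, data = dat)
    s <- coef(summary(fit))
    smry <- cbind(
      s[, 1:2, drop = FALSE],
      df = fit$df.residual,
      s[, 3:4, drop = FALSE]
    )
    singular <- FALSE
    method <- "lm"
  }
  res_sd <- sigma(fit)
  terms <- tibble::tibble(
    term = rownames(smry),
    estimate = unname(smry[, 1]),
    se = unname(smry[, 2]),
    df = unname(smry[, 3]),
    t = unname(smry[, 4]),
    p = unname(smry[, 5]),
    d = if (res_sd > 0) unname(smry[, 1]) / res_sd else NA_real_,
    eta_sq_partial = unname(smry[, 4]^2 / (smry[, 4]^2 + smry[, 3]))
  )
  structure(
    list(
      terms = terms,
      residual_sd = res_sd,
      singular = singular,
      dropped_random = dropped,
      method = method,
      n = nrow(dat),
      fit = fit
    ),
    class = "adapt_model"
  )
}

#' @export
print.adapt_model <- function(x, ...) {
  cat("Linear", if (startsWith(x$method, "lmer")) "mixed-effects" else "",
      "model (", x$method, "), n =", x$n, "\n")
  if (x$singular) cat("NOTE: singular fit (a variance component is zero)\n")
  if (length(x$dropped_random) > 0) {
    cat("Dropped random term(s) with < 2 levels:",
        paste(x$dropped_random, collapse = ", "), "\n")
  }
  print(as.data.frame(x$terms), digits = 4)
  cat("Residual SD:", format(x$residual_sd, digits = 4), "mels\n")
  invisible(x)
}

#' Paired and one-sample t-tests on participant direction means
#'
#' The participant-level inference battery for one measure: a paired t-test
#' of up-condition vs down-condition participant means, and a one-sample
#' t-test of each direction against 0. Cohen's d is `mean(diff) / sd(diff)`
#' for the paired test and `mean / sd` for the one-sample tests. Sessions
#' with a missing value in either direction are dropped from the paired test
#' only.
#'
#' @param up,down Numeric vectors of participant-session means, aligned
#'   session-by-session.
#' @return A tibble with one row per test (`test`, `n`, `mean`, `sd`, `t`,
#'   `df`, `p`, `cohen_d`). Degenerate inputs (zero variance) yield `NA`
#'   statistics with a note.
#' @export
paired_and_one_sample_tests <- function(up, down) {
  if (length(up) != length(down)) abort("`up` and `down` must be aligned vectors.")
  one <- function(x, label) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2) abort("t-tests need at least 2 observations.")
    m <- mean(x)
    s <- sd(x)
    if (s == 0) {
      return(tibble::tibble(
        test = label, n = n, mean = m, sd = s,
        t = NA_real_, df = n - 1, p = NA_real_, cohen_d = NA_real_,
        note = "zero variance; t undefined"
      ))
    }
    tt <- t.test(x, mu = 0)
    tibble::tibble(
      test = label, n = n, mean = m, sd = s,
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, cohen_d = m / s, note = NA_character_
    )
  }
  both <- !is.na(up) & !is.na(down)
  dplyr::bind_rows(
    one(up[both] - down[both], "paired_up_vs_down"),
    one(up, "one_sample_up"),
    one(down, "one_sample_down")
  )
}

#' Pair adaptation responses with the compensation that preceded them
#'
#' Builds the sign-corrected paired table the relationship analyses run on.
#' At the trial level each post-perturbation trial's adaptation response is
#' joined to the compensation response of the perturbed trial directly before
#' it. At the participant level each session contributes two points, its
#' up-direction and down-direction averages. Pairs with a missing value on
#' either side are dropped.
#'
#' @param comp_rows,adapt_rows Sign-corrected response tables for the two
#'   measures at the same level.
#' @param level `"trial"` or `"participant"`.
#' @param same_word_only At the trial level, keep only pairs in which the
#'   perturbed and post-perturbation trial used the same word (sensitivity
#'   analysis; most emulated studies mixed words across the pair).
#' @param trials A labeled trial table; required when `same_word_only = TRUE`
#'   to look up words.
#' @return A tibble with `study_id`, `participant_id`, `compensation`,
#'   `adaptation`, `magnitude_mels`, `direction` (and trial indices at the
#'   trial level).
#' @export
pair_responses <- function(comp_rows, adapt_rows,
                           level = c("trial", "participant"),
                           same_word_only = FALSE, trials = NULL) {
  level <- match.arg(level)
  if (!all(comp_rows$sign_corrected) || !all(adapt_rows$sign_corrected)) {
    abort("Relationship analyses need sign-corrected responses; see `sign_correct()`.")
  }
  if (level == "trial") {
    pairs <- dplyr::inner_join(
      dplyr::select(
        adapt_rows,
        "study_id", "participant_id",
        adapt_trial_index = "trial_index",
        prev_trial_index = "prev_trial_index",
        adaptation = "value_mels",
        magnitude_mels = "shift_magnitude_mels",
        direction = "direction"
      ),
      dplyr::select(
        comp_rows,
        "study_id", "participant_id",
        prev_trial_index = "trial_index",
        compensation = "value_mels"
      ),
      by = c("study_id", "participant_id", "prev_trial_index")
    )
    if (same_word_only) {
      if (is.null(trials)) abort("`same_word_only` needs the labeled `trials` table.")
      words <- dplyr::select(
        trials, "study_id", "participant_id", "trial_index", "word"
      )
      pairs <- pairs |>
        dplyr::left_join(
          dplyr::rename(words, adapt_trial_index = "trial_index", word_post = "word"),
          by = c("study_id", "participant_id", "adapt_trial_index")
        ) |>
        dplyr::left_join(
          dplyr::rename(words, prev_trial_index = "trial_index", word_pert = "word"),
          by = c("study_id", "participant_id", "prev_trial_index")
        ) |>
        dplyr::filter(.data$word_post == .data$word_pert)
    }
  } else {
    pairs <- dplyr::inner_join(
      dplyr::select(
        adapt_rows, "study_id", "participant_id", "direction",
        adaptation = "value_mels",
        magnitude_mels = "shift_magnitude_mels"
      ),
      dplyr::select(
        comp_rows, "study_id", "participant_id", "direction",
        compensation = "value_mels"
      ),
      by = c("study_id", "participant_id", "direction")
    )
  }
  dplyr::filter(
    pairs, !is.na(.data$compensation), !is.na(.data$adaptation),
    !is.na(.data$magnitude_mels)
  )
}

#' Mixed-effects model relating one-shot adaptation to compensation
#'
#' Fits `adaptation ~ compensation + magnitude_norm + direction +
#' compensation:magnitude_norm + (1 | participant)` on sign-corrected pairs,
#' where `magnitude_norm` is each pair's shift magnitude divided by the mean
#' magnitude over all pairs (so predictors share a common scale and the mean
#' normalized magnitude is exactly 1). Study is deliberately not a random
#' intercept: it is collinear with participant and shift magnitude. No random
#' slope of compensation is included (in the emulated analysis it prevented
#' convergence). When the magnitude has no variance (a single shift value)
#' the magnitude main effect and interaction are unidentifiable and are
#' dropped, with a note in the result.
#'
#' @param pairs Output of [pair_responses()].
#' @return An `"adapt_model"` (see [fit_direction_model()]) with an extra
#'   `note` element.
#' @export
fit_relationship_model <- function(pairs) {
  if (nrow(pairs) < 4) abort("Too few pairs to fit the relationship model.")
  dat <- data.frame(
    adaptation = pairs$adaptation,
    compensation = pairs$compensation,
    magnitude_norm = pairs$magnitude_mels / mean(pairs$magnitude_mels),
    direction = factor(pairs$direction, levels = c("down", "up")),
    participant = interaction(pairs$study_id, pairs$participant_id, drop = TRUE)
  )
  note <- NULL
  if (sd(dat$magnitude_norm) > 0) {
    form <- adaptation ~ compensation + magnitude_norm + direction +
      compensation:magnitude_norm
  } else {
    form <- adaptation ~ compensation + direction
    note <- "single shift magnitude: magnitude terms dropped (unidentifiable)"
  }
  out <- fit_lmm(form, dat, random = "participant")
  out$note <- note
  out
}

#' Per-participant compensation-adaptation correlations with Fisher pooling
#'
#' Computes Pearson's r between trial-level compensation and the one-shot
#' adaptation that followed it, separately within each participant session
#' with at least `min_pairs` pairs. The r values are Fisher-transformed
#' (`z = atanh(r)`), tested against 0 with a one-sample t-test, and the mean
#' z is back-transformed to a mean r for interpretation. An |r| of 1 (exact
#' linearity, typically degenerate input) is clamped to just inside the unit
#' interval with a warning so z stays finite.
#'
#' Also reports the secondary check that the strength of a participant's
#' correlation is unrelated to how much they adapt overall: the correlation
#' (with t-test) between per-participant r and per-participant mean
#' adaptation.
#'
#' @param pairs Trial-level output of [pair_responses()].
#' @param min_pairs Minimum pairs per included participant session (default 10).
#' @return A list of class `"adapt_correlation"`: `per_participant` (tibble
#'   of n, r, z, mean adaptation), `n_participants`, `n_positive`, `mean_z`,
#'   `mean_r`, `t`, `df`, `p`, `cohen_d`, and `vs_adaptation` (secondary
#'   test: r, t, df, p).
#' @export
per_participant_correlation <- function(pairs, min_pairs = 10) {
  per <- pairs |>
    dplyr::group_by(.data$study_id, .data$participant_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      r = if (dplyr::n() >= 2) cor(.data$compensation, .data$adaptation) else NA_real_,
      mean_adaptation = mean(.data$adaptation),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n >= min_pairs, !is.na(.data$r))
  if (nrow(per) < 2) abort("Too few eligible participants for correlation pooling.")
  clamped <- abs(per$r) >= 1
  if (any(clamped)) {
    warn(paste0(
      sum(clamped), " participant(s) with |r| = 1; clamped for the Fisher transform."
    ))
    per$r[clamped] <- sign(per$r[clamped]) * (1 - 1e-12)
  }
  per$z <- atanh(per$r)
  if (sd(per$z) > 1e-10 * max(1, abs(mean(per$z)))) {
    tt <- t.test(per$z, mu = 0)
    t_stat <- unname(tt$statistic)
    t_df <- unname(tt$parameter)
    t_p <- tt$p.value
    d <- mean(per$z) / sd(per$z)
  } else {
    # all z identical: the one-sample t is degenerate
    t_stat <- NA_real_
    t_df <- nrow(per) - 1
    t_p <- NA_real_
    d <- NA_real_
  }
  sec <- if (nrow(per) >= 3 && sd(per$r) > 1e-10 &&
             sd(per$mean_adaptation) > 1e-10) {
    s <- cor.test(per$r, per$mean_adaptation)
    tibble::tibble(
      r = unname(s$estimate), t = unname(s$statistic),
      df = unname(s$parameter), p = s$p.value
    )
  } else {
    tibble::tibble(r = NA_real_, t = NA_real_, df = NA_real_, p = NA_real_)
  }
  structure(
    list(
      per_participant = per,
      n_participants = nrow(per),
      n_positive = sum(per$r > 0),
      mean_z = mean(per$z),
      mean_r = tanh(mean(per$z)),
      t = t_stat,
      df = t_df,
      p = t_p,
      cohen_d = d,
      vs_adaptation = sec
    ),
    class = "adapt_correlation"
  )
}

#' @export
print.adapt_correlation <- function(x, ...) {
  cat("Per-participant compensation-adaptation correlation\n")
  cat("  participants:", x$n_participants,
      sprintf("(%d/%d with r > 0)\n", x$n_positive, x$n_participants))
  cat(sprintf(
    "  mean r = %.3f (Fisher-pooled), t(%d) = %.2f, p = %.3g, d = %.2f\n",
    x$mean_r, x$df, x$t, x$p, x$cohen_d
  ))
  cat(sprintf(
    "  r vs overall adaptation: r = %.3f, t(%d) = %.2f, p = %.3g\n",
    x$vs_adaptation$r, x$vs_adaptation$df, x$vs_adaptation$t, x$vs_adaptation$p
  ))
  invisible(x)
}
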