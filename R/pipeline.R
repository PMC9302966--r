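#' Pipeline configuration
#'
#' Collects every analysis constant in one place. Either `trials_path` (a
#' long-format CSV, see [read_trials()]) or `sim` (a [sim_config()]) must be
#' supplied to [run_pipeline()].
#'
#' @param trials_path Optional path to a trial table CSV.
#' @param sim Optional [sim_config()] used to simulate the input instead.
#' @param comp_window,adapt_window Analysis windows in ms (half-open).
#'   Defaults 150-250 ms (compensation) and 0-100 ms (adaptation); the
#'   alternative adaptation window `c(50, 150)` skips the consonant
#'   transition.
#' @param min_duration_ms Vowel-duration exclusion threshold (default 100).
#' @param outlier_k_sd Participant outlier threshold in SD units (default 4).
#' @param baseline_min_n Minimum trials per baseline time point (default 3).
#' @param min_coverage Minimum window coverage for a response (default 0.5).
#' @param include_post_in_comp_baseline Keep post-perturbation trials in the
#'   compensation baseline pool (default `TRUE`; they are unperturbed).
#' @param comp_baseline_role `"comp"` (all unperturbed trials) or `"adapt"`
#'   (restrict the compensation baseline to unperturbed-after-unperturbed
#'   trials as well).
#' @param same_word_pairs Restrict trial-level relationship pairs to
#'   same-word perturbed/post pairs (default `FALSE`).
#' @param cluster_t_max_ms Upper edge of the cluster-test grid (default 250).
#' @param cluster_alpha_point Per-time-point threshold alpha (default 0.05).
#' @param n_perm Cluster permutations (default 10000).
#' @param min_pairs Minimum pairs per participant for the correlation
#'   analysis (default 10).
#' @param units Unit of a bare `f1` column when reading `trials_path`.
#' @param seed Seed for the permutation draw (and, if `sim` carries no seed,
#'   for simulation).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(trials_path = NULL,
                            sim = NULL,
                            comp_window = c(150, 250),
                            adapt_window = c(0, 100),
                            min_duration_ms = 100,
                            outlier_k_sd = 4,
                            baseline_min_n = 3,
                            min_coverage = 0.5,
                            include_post_in_comp_baseline = TRUE,
                            comp_baseline_role = c("comp", "adapt"),
                            same_word_pairs = FALSE,
                            cluster_t_max_ms = 250,
                            cluster_alpha_point = 0.05,
                            n_perm = 10000,
                            min_pairs = 10,
                            units = "mels",
                            seed = 1L) {
  comp_baseline_role <- match.arg(comp_baseline_role)
  stopifnot(
    length(comp_window) == 2, comp_window[1] < comp_window[2],
    length(adapt_window) == 2, adapt_window[1] < adapt_window[2],
    min_duration_ms > 0, outlier_k_sd > 0, baseline_min_n >= 1,
    min_coverage >= 0, min_coverage <= 1
  )
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the complete trial-to-inference chain: read or simulate the trial
#' table; label roles; drop short vowels; build participant- and
#' word-specific baseline trajectories; normalize perturbed and
#' post-perturbation trials; compute trial- and participant-level windowed
#' responses; screen outlier participants; and run the inference battery
#' (direction mixed models, paired/one-sample t-tests, cluster-based
#' permutation tests over 0-250 ms, relationship models at both levels, and
#' Fisher-pooled per-participant correlations). Fully reproducible from the
#' configuration.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return A list of class `"adapt_report"` with elements `qc` (counts at
#'   every stage), `responses` (trial/participant tables, raw and
#'   sign-corrected), `models`, `tests`, `clusters`, `relationship`,
#'   `correlation`, and `config`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) inform(paste0(...))
  qc <- list()

  # -- input ----------------------------------------------------------------
  if (!is.null(config$sim)) {
    say("Simulating experiment (seed ", config$sim$seed, ")")
    experiment <- simulate_experiment(config$sim)
    trials <- experiment$trials
  } else if (!is.null(config$trials_path)) {
    say("Reading trials from ", config$trials_path)
    trials <- read_trials(config$trials_path, units = config$units)
    experiment <- NULL
  } else {
    abort("Config must carry either `sim` or `trials_path`.")
  }
  qc$n_trials_input <- nrow(trials)

  # -- label and filter -----------------------------------------------------
  labeled <- label_trials(trials)
  filt <- filter_short_vowels(labeled, config$min_duration_ms)
  labeled <- filt$kept
  qc$n_short_vowel_dropped <- filt$n_dropped
  qc$role_counts <- c(
    perturbed_up = sum(labeled$perturbed_up),
    perturbed_down = sum(labeled$perturbed_down),
    post_up = sum(labeled$post_up),
    post_down = sum(labeled$post_down),
    baseline_comp = sum(labeled$baseline_comp),
    baseline_adapt = sum(labeled$baseline_adapt)
  )
  say(
    "Labeled ", nrow(labeled), " trials (dropped ", filt$n_dropped,
    " short vowels)"
  )

  # -- baselines and normalization ------------------------------------------
  base_comp <- compute_baselines(
    labeled,
    role = config$comp_baseline_role,
    min_n = config$baseline_min_n,
    include_post_trials = config$include_post_in_comp_baseline
  )
  base_adapt <- compute_baselines(
    labeled, role = "adapt", min_n = config$baseline_min_n
  )
  pert <- labeled[labeled$perturbed_up | labeled$perturbed_down, ]
  post <- labeled[labeled$post_up | labeled$post_down, ]
  norm_comp <- normalize_trials(pert, base_comp)
  norm_adapt <- normalize_trials(post, base_adapt)
  qc$n_comp_no_baseline <- norm_comp$n_no_baseline
  qc$n_adapt_no_baseline <- norm_adapt$n_no_baseline

  # -- responses ------------------------------------------------------------
  comp_trial <- trial_responses(
    norm_comp$trials, "compensation",
    window = config$comp_window, min_coverage = config$min_coverage
  )
  adapt_trial <- trial_responses(
    norm_adapt$trials, "adaptation",
    window = config$adapt_window, min_coverage = config$min_coverage
  )
  comp_ppt <- participant_responses(
    norm_comp$trials, "compensation",
    window = config$comp_window, min_coverage = config$min_coverage
  )
  adapt_ppt <- participant_responses(
    norm_adapt$trials, "adaptation",
    window = config$adapt_window, min_coverage = config$min_coverage
  )
  qc$n_comp_responses <- sum(!is.na(comp_trial$value_mels))
  qc$n_adapt_responses <- sum(!is.na(adapt_trial$value_mels))

  # -- participant outlier screen -------------------------------------------
  ppt_means <- dplyr::full_join(
    summarise_session(sign_correct(comp_ppt), "compensation"),
    summarise_session(sign_correct(adapt_ppt), "adaptation"),
    by = c("study_id", "participant_id")
  )
  screen <- exclude_outlier_participants(ppt_means, config$outlier_k_sd)
  qc$n_sessions <- nrow(ppt_means)
  qc$n_outlier_sessions <- nrow(screen$excluded)
  if (qc$n_outlier_sessions > 0) {
    say(
      "Excluding ", qc$n_outlier_sessions, " outlier session(s): ",
      paste(
        paste(screen$excluded$study_id, screen$excluded$participant_id, sep = "/"),
        collapse = ", "
      )
    )
  }
  keep_session <- function(tbl) {
    dplyr::semi_join(
      tbl, screen$kept[, c("study_id", "participant_id")],
      by = c("study_id", "participant_id")
    )
  }
  comp_trial <- keep_session(comp_trial)
  adapt_trial <- keep_session(adapt_trial)
  comp_ppt <- keep_session(comp_ppt)
  adapt_ppt <- keep_session(adapt_ppt)
  norm_comp$trials <- keep_session(norm_comp$trials)
  norm_adapt$trials <- keep_session(norm_adapt$trials)

  # -- direction models and participant-level tests -------------------------
  say("Fitting direction models")
  models <- list(
    compensation = fit_direction_model(comp_trial),
    adaptation = fit_direction_model(adapt_trial)
  )
  tests <- list(
    compensation = direction_tests(comp_ppt),
    adaptation = direction_tests(adapt_ppt)
  )

  # -- cluster permutation tests --------------------------------------------
  say("Cluster permutation tests (", config$n_perm, " permutations)")
  cluster_seed <- substream_seed(config$seed, "permutation")
  conditions <- list(
    comp_up = norm_comp$trials[norm_comp$trials$perturbed_up, ],
    comp_down = norm_comp$trials[norm_comp$trials$perturbed_down, ],
    adapt_up = norm_adapt$trials[norm_adapt$trials$post_up, ],
    adapt_down = norm_adapt$trials[norm_adapt$trials$post_down, ]
  )
  mats <- lapply(
    conditions, condition_average_matrix, t_max_ms = config$cluster_t_max_ms
  )
  clusters <- list()
  for (nm in names(mats)) {
    clusters[[nm]] <- cluster_permutation(
      mats[[nm]]$matrix,
      time_ms = mats[[nm]]$time_ms,
      alpha_point = config$cluster_alpha_point,
      n_perm = config$n_perm,
      seed = cluster_seed + match(nm, names(mats))
    )
  }
  clusters$comp_between <- paired_cluster(
    mats$comp_up, mats$comp_down, config, cluster_seed + 11
  )
  clusters$adapt_between <- paired_cluster(
    mats$adapt_up, mats$adapt_down, config, cluster_seed + 12
  )

  # -- relationship analyses ------------------------------------------------
  say("Relationship models and correlations")
  comp_trial_sc <- sign_correct(comp_trial)
  adapt_trial_sc <- sign_correct(adapt_trial)
  trial_pairs <- pair_responses(
    comp_trial_sc, adapt_trial_sc,
    level = "trial",
    same_word_only = config$same_word_pairs, trials = labeled
  )
  ppt_pairs <- pair_responses(
    sign_correct(comp_ppt), sign_correct(adapt_ppt),
    level = "participant"
  )
  relationship <- list(
    trial = fit_relationship_model(trial_pairs),
    participant = fit_relationship_model(ppt_pairs)
  )
  correlation <- per_participant_correlation(trial_pairs, config$min_pairs)
  qc$n_trial_pairs <- nrow(trial_pairs)
  qc$n_correlation_participants <- correlation$n_participants

  structure(
    list(
      qc = qc,
      responses = list(
        trial = dplyr::bind_rows(comp_trial, adapt_trial),
        trial_sign_corrected = dplyr::bind_rows(comp_trial_sc, adapt_trial_sc),
        participant = dplyr::bind_rows(comp_ppt, adapt_ppt),
        participant_means = ppt_means,
        pairs_trial = trial_pairs,
        pairs_participant = ppt_pairs
      ),
      normalized = list(comp = norm_comp$trials, adapt = norm_adapt$trials),
      condition_matrices = mats,
      models = models,
      tests = tests,
      clusters = clusters,
      relationship = relationship,
      correlation = correlation,
      outliers = screen$excluded,
      config = config,
      experiment = experiment
    ),
    class = "adapt_report"
  )
}

# sign-corrected direction-collapsed session means for the outlier screen
summarise_session <- function(ppt_rows_sc, name) {
  out <- ppt_rows_sc |>
    dplyr::group_by(.data$study_id, .data$participant_id) |>
    dplyr::summarise(
      value = mean(.data$value_mels, na.rm = TRUE),
      .groups = "drop"
    )
  names(out)[names(out) == "value"] <- name
  out
}

direction_tests <- function(ppt_rows) {
  wide <- ppt_rows |>
    dplyr::select("study_id", "participant_id", "direction", "value_mels") |>
    tidyr::pivot_wider(names_from = "direction", values_from = "value_mels")
  if (!all(c("up", "down") %in% names(wide))) {
    abort("Both directions are needed for the participant-level tests.")
  }
  paired_and_one_sample_tests(wide$up, wide$down)
}

paired_cluster <- function(mat_up, mat_down, config, seed) {
  up <- mat_up$sessions
  up$row_up <- seq_len(nrow(up))
  down <- mat_down$sessions
  down$row_down <- seq_len(nrow(down))
  common <- dplyr::inner_join(up, down, by = c("study_id", "participant_id"))
  cluster_permutation(
    mat_up$matrix[common$row_up, , drop = FALSE],
    mat_down$matrix[common$row_down, , drop = FALSE],
    time_ms = mat_up$time_ms,
    alpha_point = config$cluster_alpha_point,
    n_perm = config$n_perm,
    seed = seed
  )
}

#' @export
print.adapt_report <- function(x, ...) {
  cat("One-shot adaptation analysis report\n")
  cat("-----------------------------------\n")
  cat("Trials in:", x$qc$n_trials_input,
      "| short vowels dropped:", x$qc$n_short_vowel_dropped,
      "| sessions:", x$qc$n_sessions,
      "| outlier sessions:", x$qc$n_outlier_sessions, "\n")
  cat("\nTrial-level direction models (beta = up - down):\n")
  for (nm in names(x$models)) {
    b <- x$models[[nm]]$terms[x$models[[nm]]$terms$term == "directionup", ]
    cat(sprintf(
      "  %-13s beta = %6.2f mels, SE = %.2f, t(%.1f) = %.2f, p = %.3g, d = %.2f\n",
      nm, b$estimate, b$se, b$df, b$t, b$p, abs(b$d)
    ))
  }
  cat("\nParticipant-level paired tests (up vs down):\n")
  for (nm in names(x$tests)) {
    p <- x$tests[[nm]][x$tests[[nm]]$test == "paired_up_vs_down", ]
    cat(sprintf(
      "  %-13s mean diff = %6.2f mels, t(%.0f) = %.2f, p = %.3g, d = %.2f\n",
      nm, p$mean, p$df, p$t, p$p, abs(p$cohen_d)
    ))
  }
  cat("\nSignificant clusters (p < 0.05):\n")
  for (nm in names(x$clusters)) {
    cl <- x$clusters[[nm]]$clusters
    sig <- cl[cl$p_perm < 0.05, , drop = FALSE]
    if (nrow(sig) > 0) {
      for (i in seq_len(nrow(sig))) {
        cat(sprintf(
          "  %-13s %g-%g ms (mass %.1f, p = %.4f)\n",
          nm, sig$start_ms[i], sig$end_ms[i], sig$mass[i], sig$p_perm[i]
        ))
      }
    }
  }
  cat("\nRelationship (sign-corrected):\n")
  for (nm in names(x$relationship)) {
    b <- x$relationship[[nm]]$terms[
      x$relationship[[nm]]$terms$term == "compensation", ]
    cat(sprintf(
      "  %-13s compensation beta = %.3f, SE = %.3f, p = %.3g\n",
      nm, b$estimate, b$se, b$p
    ))
  }
  cat(sprintf(
    "  per-participant mean r = %.3f (t(%.0f) = %.2f, p = %.3g; %d/%d r > 0)\n",
    x$correlation$mean_r, x$correlation$df, x$correlation$t, x$correlation$p,
    x$correlation$n_positive, x$correlation$n_participants
  ))
  invisible(x)
}

#' Write the report bundle to disk
#'
#' Serializes the main tables of an [run_pipeline()] report as CSV files plus
#' a human-readable summary, under `dir`.
#'
#' @param report An `"adapt_report"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    readr::write_csv(x, file.path(dir, name), progress = FALSE)
  }
  w(report$responses$trial, "responses_trial.csv")
  w(report$responses$participant, "responses_participant.csv")
  w(report$responses$pairs_trial, "pairs_trial.csv")
  model_rows <- purrr::imap_dfr(
    c(report$models, stats::setNames(
      report$relationship, paste0("relationship_", names(report$relationship))
    )),
    function(m, nm) dplyr::mutate(m$terms, model = nm, .before = 1)
  )
  w(model_rows, "model_terms.csv")
  test_rows <- purrr::imap_dfr(
    report$tests, function(t, nm) dplyr::mutate(t, measure = nm, .before = 1)
  )
  w(test_rows, "t_tests.csv")
  cluster_rows <- purrr::imap_dfr(
    report$clusters,
    function(cl, nm) {
      if (nrow(cl$clusters) == 0) return(NULL)
      dplyr::mutate(cl$clusters, contrast = nm, .before = 1)
    }
  )
  if (nrow(cluster_rows) == 0) {
    cluster_rows <- tibble::tibble(
      contrast = character(), start_ms = numeric(), end_ms = numeric(),
      n_points = integer(), mass = numeric(), sign = numeric(),
      p_perm = numeric()
    )
  }
  w(cluster_rows, "clusters.csv")
  w(report$correlation$per_participant, "correlations_participant.csv")
  qc <- report$qc
  qc_tbl <- tibble::tibble(
    stat = c(
      "n_trials_input", "n_short_vowel_dropped", names(qc$role_counts),
      "n_comp_no_baseline", "n_adapt_no_baseline", "n_comp_responses",
      "n_adapt_responses", "n_sessions", "n_outlier_sessions",
      "n_trial_pairs", "n_correlation_participants"
    ),
    value = c(
      qc$n_trials_input, qc$n_short_vowel_dropped, unname(qc$role_counts),
      qc$n_comp_no_baseline, qc$n_adapt_no_baseline, qc$n_comp_responses,
      qc$n_adapt_responses, qc$n_sessions, qc$n_outlier_sessions,
      qc$n_trial_pairs, qc$n_correlation_participants
    )
  )
  w(qc_tbl, "qc.csv")
  con <- file(file.path(dir, "report.txt"), open = "wt")
  sink(con)
  on.exit({
    sink()
    close(con)
  }, add = TRUE)
  print(report)
  invisible(dir)
}
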