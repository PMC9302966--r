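#' Plot condition-average normalized trajectories
#'
#' Grand-average normalized F1 timecourses (mean across participant
#' condition averages, with standard-error ribbons) for the four conditions:
#' up/down perturbed trials and post-up/post-down trials. Horizontal bars
#' under the traces mark significant clusters from the permutation tests.
#'
#' @param report An `"adapt_report"` from [run_pipeline()].
#' @param alpha Cluster significance level for the bars (default 0.05).
#' @return A ggplot object.
#' @export
plot_condition_trajectories <- function(report, alpha = 0.05) {
  mats <- report$condition_matrices
  cond_levels <- c("comp_up", "comp_down", "adapt_up", "adapt_down")
  grand <- purrr::imap_dfr(mats, function(m, nm) {
    x <- m$matrix
    n <- colSums(!is.na(x))
    keep <- n >= 2
    tibble::tibble(
      condition = nm,
      time_ms = m$time_ms[keep],
      mean = colMeans(x, na.rm = TRUE)[keep],
      se = apply(x, 2, sd, na.rm = TRUE)[keep] / sqrt(n[keep])
    )
  })
  grand$condition <- factor(grand$condition, levels = cond_levels)
  bars <- purrr::imap_dfr(
    report$clusters[cond_levels],
    function(cl, nm) {
      sig <- cl$clusters[cl$clusters$p_perm < alpha, , drop = FALSE]
      if (nrow(sig) == 0) return(NULL)
      tibble::tibble(condition = nm, start_ms = sig$start_ms, end_ms = sig$end_ms)
    }
  )
  y_bar <- min(grand$mean - grand$se, na.rm = TRUE)
  p <- ggplot2::ggplot(grand, ggplot2::aes(
    x = .data$time_ms, y = .data$mean,
    colour = .data$condition, fill = .data$condition
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Time from vowel onset (ms)",
      y = "Normalized F1 (mels)",
      colour = "Condition", fill = "Condition"
    ) +
    ggplot2::theme_minimal()
  if (nrow(bars) > 0) {
    bars$condition <- factor(bars$condition, levels = cond_levels)
    bars$y <- y_bar * (1.05 + 0.05 * as.integer(bars$condition))
    p <- p + ggplot2::geom_segment(
      data = bars,
      ggplot2::aes(
        x = .data$start_ms, xend = .data$end_ms, y = .data$y, yend = .data$y,
        colour = .data$condition
      ),
      linewidth = 1.5, inherit.aes = FALSE
    )
  }
  p
}

#' Scatter plot of compensation vs one-shot adaptation
#'
#' Sign-corrected responses, one point per participant-direction average
#' (`level = "participant"`, coloured by mean shift magnitude) or per
#' perturbed/post trial pair (`level = "trial"`), with the fitted
#' compensation slope from the relationship model.
#'
#' @param report An `"adapt_report"`.
#' @param level `"participant"` or `"trial"`.
#' @return A ggplot object.
#' @export
plot_relationship <- function(report, level = c("participant", "trial")) {
  level <- match.arg(level)
  pairs <- if (level == "participant") {
    report$responses$pairs_participant
  } else {
    report$responses$pairs_trial
  }
  terms <- report$relationship[[level]]$terms
  slope <- terms$estimate[terms$term == "compensation"]
  intercept <- terms$estimate[terms$term == "(Intercept)"]
  ggplot2::ggplot(pairs, ggplot2::aes(
    x = .data$compensation, y = .data$adaptation,
    colour = .data$magnitude_mels
  )) +
    ggplot2::geom_point(alpha = if (level == "trial") 0.2 else 0.8) +
    ggplot2::geom_abline(slope = slope, intercept = intercept) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(
      x = "Compensation (mels, sign-corrected)",
      y = "One-shot adaptation (mels, sign-corrected)",
      colour = "Shift (mels)"
    ) +
    ggplot2::theme_minimal()
}
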