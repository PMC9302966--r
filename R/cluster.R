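#' Cluster-based permutation test over a trajectory timecourse
#'
#' Tests where along the vowel a set of per-participant average normalized
#' trajectories differs from zero (`y = NULL`) or where two within-participant
#' conditions differ from each other (paired; `y` given, the test runs on
#' `x - y`). The procedure controls the family-wise error rate over time
#' points without assuming independence across them:
#' \enumerate{
#'   \item a one-sample t statistic is computed across participants at every
#'     time point;
#'   \item time points with `|t|` above the two-tailed critical value at
#'     `alpha_point` are marked, and maximal runs of consecutive marked
#'     points with the same sign form clusters whose mass is the sum of
#'     their t values;
#'   \item a null distribution of the maximum absolute cluster mass is built
#'     by randomly flipping the sign of each participant's whole trajectory
#'     (for the paired contrast this is exactly a condition-label swap), and
#'     each observed cluster's p is the proportion of the null at or above
#'     its absolute mass, with the add-one convention
#'     `p = (1 + #exceedances) / (1 + n_perm)`.
#' }
#'
#' Trajectories shorter than the grid contribute only at the time points they
#' cover; trailing time points with fewer than 3 contributing participants
#' are dropped from the tested range with a warning. With
#' `n_perm = "exhaustive"` all `2^n` sign assignments are enumerated
#' (including the identity) and p values are exact proportions of that full
#' set.
#'
#' @param x Numeric matrix, participants x time points (NA-padded), e.g.
#'   per-participant condition-average normalized trajectories on the 0-250 ms
#'   grid.
#' @param y Optional matrix of the same shape for a paired between-condition
#'   contrast.
#' @param time_ms Time (ms) of each column; defaults to `0, step, ...` with
#'   `step_ms`.
#' @param step_ms Grid step used when `time_ms` is absent.
#' @param alpha_point Two-tailed per-time-point alpha forming clusters
#'   (default 0.05).
#' @param n_perm Number of random sign flips (default 10000), or
#'   `"exhaustive"`.
#' @param seed Optional integer seed for the permutation draw (local to this
#'   call).
#' @return A list of class `"adapt_clusters"`: `time_ms`, `t` (per time
#'   point), `df`, `t_crit`, `clusters` (tibble: start/end time, length,
#'   mass, sign, p_perm), `n_perm`, `alpha_point`, `contrast`.
#' @export
cluster_permutation <- function(x, y = NULL, time_ms = NULL, step_ms = 5,
                                alpha_point = 0.05, n_perm = 10000,
                                seed = NULL) {
  contrast <- if (is.null(y)) "vs_zero" else "between"
  if (!is.null(y)) {
    stopifnot(all(dim(x) == dim(y)))
    x <- x - y
  }
  x <- as.matrix(x)
  if (is.null(time_ms)) time_ms <- (seq_len(ncol(x)) - 1) * step_ms
  stopifnot(length(time_ms) == ncol(x))

  n_at <- colSums(!is.na(x))
  usable <- n_at >= 3
  if (!any(usable)) abort("No time point has >= 3 contributing participants.")
  if (!all(usable)) {
    warn(paste0(
      sum(!usable), " time point(s) with < 3 participants dropped from the tested range."
    ))
    x <- x[, usable, drop = FALSE]
    time_ms <- time_ms[usable]
    n_at <- n_at[usable]
  }

  x0 <- x
  x0[is.na(x0)] <- 0
  ss <- colSums(x^2, na.rm = TRUE)
  t_of_signs <- function(s) {
    # s: n-vector of +/-1; sign flips leave NA positions and sums of squares
    m <- as.vector(crossprod(x0, s)) / n_at
    v <- (ss - n_at * m^2) / (n_at - 1)
    v[v < 0] <- 0
    ifelse(v == 0, ifelse(m == 0, 0, sign(m) * Inf), m / sqrt(v / n_at))
  }
  n <- nrow(x)
  t_obs <- t_of_signs(rep(1, n))
  df <- n_at - 1
  t_crit <- qt(1 - alpha_point / 2, df)

  clusters_of <- function(tv, crit) {
    supra <- abs(tv) > crit
    sgn <- sign(tv)
    out <- list()
    i <- 1
    while (i <= length(tv)) {
      if (supra[i]) {
        j <- i
        while (j < length(tv) && supra[j + 1] && sgn[j + 1] == sgn[i]) j <- j + 1
        out[[length(out) + 1]] <- c(start = i, end = j, mass = sum(tv[i:j]))
        i <- j + 1
      } else {
        i <- i + 1
      }
    }
    out
  }
  max_mass_of <- function(tv, crit) {
    cl <- clusters_of(tv, crit)
    if (length(cl) == 0) 0 else max(abs(vapply(cl, `[[`, numeric(1), "mass")))
  }

  obs_clusters <- clusters_of(t_obs, t_crit)

  exhaustive <- identical(n_perm, "exhaustive")
  if (exhaustive) {
    if (n > 20) abort("Exhaustive enumeration is limited to n <= 20 participants.")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null_max <- apply(signs, 1, function(s) max_mass_of(t_of_signs(s), t_crit))
    n_eff <- nrow(signs)
  } else {
    stopifnot(is.numeric(n_perm), n_perm >= 1)
    old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(restore_seed(old_seed), add = TRUE)
    if (!is.null(seed)) set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
    # all permutation t statistics in one crossproduct
    m_all <- crossprod(x0, signs) / n_at
    v_all <- (ss - n_at * m_all^2) / (n_at - 1)
    v_all[v_all < 0] <- 0
    t_all <- m_all / sqrt(v_all / n_at)
    t_all[!is.finite(t_all)] <- ifelse(
      m_all[!is.finite(t_all)] == 0, 0, sign(m_all[!is.finite(t_all)]) * Inf
    )
    null_max <- vapply(
      seq_len(n_perm), function(k) max_mass_of(t_all[, k], t_crit), numeric(1)
    )
    n_eff <- n_perm
  }

  cl_tbl <- if (length(obs_clusters) == 0) {
    tibble::tibble(
      start_ms = numeric(), end_ms = numeric(), n_points = integer(),
      mass = numeric(), sign = numeric(), p_perm = numeric()
    )
  } else {
    purrr::map_dfr(obs_clusters, function(cl) {
      mass <- cl[["mass"]]
      p <- if (exhaustive) {
        mean(null_max >= abs(mass) - 1e-12)
      } else {
        (1 + sum(null_max >= abs(mass) - 1e-12)) / (1 + n_eff)
      }
      tibble::tibble(
        start_ms = time_ms[cl[["start"]]],
        end_ms = time_ms[cl[["end"]]],
        n_points = as.integer(cl[["end"]] - cl[["start"]] + 1),
        mass = mass,
        sign = sign(mass),
        p_perm = p
      )
    })
  }
  structure(
    list(
      time_ms = time_ms,
      t = t_obs,
      df = df,
      t_crit = t_crit,
      clusters = cl_tbl,
      n_perm = n_eff,
      alpha_point = alpha_point,
      contrast = contrast
    ),
    class = "adapt_clusters"
  )
}

#' @export
print.adapt_clusters <- function(x, ...) {
  cat("Cluster-based permutation test (", x$contrast, "), ",
      x$n_perm, " permutations\n", sep = "")
  cat("  tested range:", min(x$time_ms), "-", max(x$time_ms), "ms;",
      "point threshold alpha =", x$alpha_point, "\n")
  if (nrow(x$clusters) == 0) {
    cat("  no suprathreshold clusters\n")
  } else {
    print(as.data.frame(x$clusters), digits = 4)
  }
  invisible(x)
}

#' Stack participant condition averages onto a common grid
#'
#' Helper for [cluster_permutation()]: turns normalized trials into a
#' participants x time matrix of condition-average trajectories over
#' `[0, t_max_ms]`.
#'
#' @param normalized Output `$trials` of [normalize_trials()] restricted to
#'   one condition's trials.
#' @param t_max_ms Upper edge of the grid (default 250 ms).
#' @param min_n Passed to [participant_average_trajectory()].
#' @return A list with `matrix` (rows = participant sessions, NA-padded),
#'   `time_ms`, and `sessions` (tibble aligning rows to sessions).
#' @export
condition_average_matrix <- function(normalized, t_max_ms = 250, min_n = 1) {
  step <- normalized$step_ms[1]
  n_col <- floor(t_max_ms / step) + 1
  avg <- normalized |>
    dplyr::group_by(.data$study_id, .data$participant_id) |>
    dplyr::summarise(
      avg = list(participant_average_trajectory(.data$norm, min_n = min_n)),
      .groups = "drop"
    )
  keep <- !vapply(avg$avg, is.null, logical(1))
  avg <- avg[keep, , drop = FALSE]
  list(
    matrix = traj_matrix(avg$avg, ncol = n_col),
    time_ms = (seq_len(n_col) - 1) * step,
    sessions = avg[, c("study_id", "participant_id")]
  )
}
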