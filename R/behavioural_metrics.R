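#' Summarize one subject's behavioural trials
#'
#' Computes the per-subject behavioural summary for one condition:
#' percentage of trials with vection reported, median onset latency and
#' median vection duration over vection-present trials, and median
#' strength rating over all trials of the condition. Practice trials are
#' excluded.
#'
#' @param trials A trial table from [generate_behaviour()] (or any data
#'   frame with the same columns).
#' @param condition `"coherent"` or `"incoherent"`.
#' @param direction Optional `"CW"`/`"CCW"` filter (used when verifying
#'   that directions can be collapsed).
#' @return A one-row data frame: `condition`, `n_trials`, `presence_pct`,
#'   `median_onset_s`, `median_duration_s`, `median_strength`, and
#'   `onset_defined` (FALSE when no vection-present trial exists, in
#'   which case the onset/duration medians are `NA`).
#' @export
summarize_subject <- function(trials, condition, direction = NULL) {
  tr <- trials[!trials$is_practice & trials$condition == condition, ,
               drop = FALSE]
  if (!is.null(direction)) {
    tr <- tr[tr$direction == direction, , drop = FALSE]
  }
  if (nrow(tr) == 0L) {
    stop("no trials of condition '", condition, "'", call. = FALSE)
  }
  present <- tr[tr$vection_present, , drop = FALSE]
  data.frame(
    condition = condition,
    n_trials = nrow(tr),
    presence_pct = 100 * nrow(present) / nrow(tr),
    median_onset_s = if (nrow(present)) stats::median(present$vection_onset_s)
                     else NA_real_,
    median_duration_s = if (nrow(present)) {
      stats::median(present$vection_offset_s - present$vection_onset_s)
    } else NA_real_,
    median_strength = stats::median(tr$strength),
    onset_defined = nrow(present) > 0L,
    stringsAsFactors = FALSE
  )
}

#' Rank-based effect size r = Z / sqrt(N)
#'
#' @param z_value Standard-normal test statistic.
#' @param n_obs Number of observations entering the effect size (for the
#'   two-group comparisons here: the per-group subject count).
#' @return Signed effect size r.
#' @examples
#' effect_size_r(-1.25, 25)  # -0.25
#' @export
effect_size_r <- function(z_value, n_obs) {
  stopifnot(n_obs > 0)
  z_value / sqrt(n_obs)
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Two-sample rank-sum test via the continuity-corrected normal
#' approximation with mid-ranks and tie-corrected variance, as
#' appropriate for integer-valued behavioural scores. The effect size is r = Z / sqrt(`n_obs`), where
#' `n_obs` defaults to the per-group subject count.
#'
#' @param values_a,values_b Per-subject values for the two groups (each
#'   length >= 2).
#' @param n_obs Observation count used in the effect size; default
#'   `length(values_a)`.
#' @return An object of class `vection_test` with `test_name`
#'   (`"rank-sum"`), `z_value`, `p_value`, `effect_r`, `n_obs` and a
#'   `degenerate` flag (all values tied across both groups).
#' @export
compare_groups <- function(values_a, values_b, n_obs = length(values_a)) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2,
            all(is.finite(values_a)), all(is.finite(values_b)))
  na <- length(values_a)
  nb <- length(values_b)
  nn <- na + nb
  rk <- rank(c(values_a, values_b))
  w <- sum(rk[seq_len(na)])
  mu <- na * (nn + 1) / 2
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
  v <- na * nb / 12 * ((nn + 1) - tie_term)
  degenerate <- v <= 0
  z <- if (degenerate) 0 else {
    num <- w - mu
    (num - sign(num) * 0.5) / sqrt(v)  # continuity correction
  }
  p <- if (degenerate) 1 else 2 * stats::pnorm(-abs(z))
  new_vection_test("rank-sum", z, p, effect_size_r(z, n_obs), n_obs,
                   degenerate)
}

#' Wilcoxon signed-rank comparison of paired direction measures
#'
#' Paired signed-rank test (CW versus CCW subject-level values) via the
#' continuity-corrected normal approximation with mid-ranks,
#' zero-difference exclusion and tie-corrected variance. The returned p value is Bonferroni-adjusted by
#' `family_size`, the number of screening tests run (4 behavioural
#' measures x 2 conditions x 2 groups by default), and capped at 1.
#'
#' @param values_cw,values_ccw Paired per-subject values.
#' @param family_size Bonferroni family size. Default 16.
#' @param n_obs Observation count for the effect size; defaults to the
#'   number of pairs.
#' @return A `vection_test` (`test_name = "signed-rank"`) whose `p_value`
#'   is the adjusted p; the raw p is kept as `p_raw`. `degenerate` is set
#'   when fewer than 2 non-zero pairs remain.
#' @export
compare_directions <- function(values_cw, values_ccw, family_size = 16,
                               n_obs = length(values_cw)) {
  stopifnot(length(values_cw) == length(values_ccw), family_size >= 1)
  d <- values_cw - values_ccw
  d <- d[d != 0]
  m <- length(d)
  if (m < 2L) {
    out <- new_vection_test("signed-rank", 0, 1, 0, n_obs, TRUE)
    out$p_raw <- 1
    return(out)
  }
  rk <- rank(abs(d))
  w_pos <- sum(rk[d > 0])
  mu <- m * (m + 1) / 4
  ties <- table(rk)
  v <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
  degenerate <- v <= 0
  z <- if (degenerate) 0 else {
    num <- w_pos - mu
    (num - sign(num) * 0.5) / sqrt(v)  # continuity correction
  }
  p_raw <- if (degenerate) 1 else 2 * stats::pnorm(-abs(z))
  out <- new_vection_test("signed-rank", z, min(1, p_raw * family_size),
                          effect_size_r(z, n_obs), n_obs, degenerate)
  out$p_raw <- p_raw
  out
}

new_vection_test <- function(test_name, z, p, r, n_obs, degenerate) {
  structure(list(test_name = test_name, z_value = z, p_value = p,
                 effect_r = r, n_obs = n_obs, degenerate = degenerate),
            class = "vection_test")
}

#' @export
print.vection_test <- function(x, ...) {
  cat(sprintf("%s test: Z = %.3f, p = %.4g, r = %.3f (n_obs = %d)%s\n",
              x$test_name, x$z_value, x$p_value, x$effect_r, x$n_obs,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Habituation of vection strength across trials
#'
#' Tests whether the subjective strength rating drifts over the course of
#' the experiment. Each subject's strengths are centred by subtracting
#' that subject's median strength over all main trials; centred strengths
#' of all subjects are pooled and Spearman-rank correlated against the
#' within-condition trial position. Also reports the mean (over subjects)
#' of mean(first 10 trials) - mean(last 10 trials), a positive value
#' indicating decreasing strength.
#'
#' @param all_subject_trials List of trial tables, one per subject.
#' @param condition `"coherent"` or `"incoherent"`.
#' @param n_edge Number of trials in the first/last contrast (default 10).
#' @return An object of class `spearman_result`: `rho`, `p_value`,
#'   `first10_last10_delta`, `n_pairs`, and `constant` (TRUE when the
#'   pooled strengths have no variance, in which case `rho` is `NA`).
#' @export
habituation_correlation <- function(all_subject_trials, condition,
                                    n_edge = 10L) {
  stopifnot(length(all_subject_trials) >= 2)
  pos_all <- numeric(0)
  str_all <- numeric(0)
  deltas <- numeric(0)
  for (trials in all_subject_trials) {
    tr <- trials[!trials$is_practice, , drop = FALSE]
    sel <- tr[tr$condition == condition, , drop = FALSE]
    if (nrow(sel) < 2L) {
      stop("each subject needs at least 2 trials of the condition",
           call. = FALSE)
    }
    centred <- sel$strength - stats::median(tr$strength)
    pos <- seq_len(nrow(sel))
    pos_all <- c(pos_all, pos)
    str_all <- c(str_all, centred)
    k <- min(n_edge, nrow(sel) %/% 2L)
    deltas <- c(deltas, mean(centred[seq_len(k)]) -
                  mean(centred[seq.int(nrow(sel) - k + 1L, nrow(sel))]))
  }
  constant <- stats::sd(str_all) == 0
  if (constant) {
    rho <- NA_real_
    p <- NA_real_
  } else {
    ct <- suppressWarnings(
      stats::cor.test(pos_all, str_all, method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(list(rho = rho, p_value = p,
                 first10_last10_delta = mean(deltas),
                 n_pairs = length(str_all), constant = constant),
            class = "spearman_result")
}

#' @export
print.spearman_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, p = %.4g (n = %d); first-last delta = %.3f%s\n",
              x$rho, x$p_value, x$n_pairs, x$first10_last10_delta,
              if (x$constant) " [constant input]" else ""))
  invisible(x)
}

#' Boxplot-whisker outlier rule
#'
#' Flags values beyond `w` interquartile ranges outside the quartiles:
#' `x > q3 + w (q3 - q1)` or `x < q1 - w (q3 - q1)`, with `w = 1.5` the
#' maximum whisker length.
#'
#' @param values Numeric vector (length >= 4).
#' @param w Whisker length multiplier.
#' @return Logical mask, `TRUE` for outliers.
#' @export
flag_outliers <- function(values, w = 1.5) {
  if (length(values) < 4L) {
    stop("at least 4 values are required for the quartile rule",
         call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, na.rm = TRUE)
  iqr <- q[2] - q[1]
  values > q[2] + w * iqr | values < q[1] - w * iqr
}
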