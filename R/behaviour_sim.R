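#' Generate behavioural trial outcomes for one synthetic session
#'
#' Builds the full trial table of one session: practice trials followed by
#' the main trials, conditions and directions balanced per the design and
#' randomized within presentation blocks. For each trial, vection presence
#' is drawn from the profile's per-condition probability; onset latency
#' and duration are drawn from truncated log-normal distributions (onset
#' within the rotation window, offset clipped to the end of rotation);
#' the 0-10 strength rating decreases across main trials by the profile's
#' habituation slope. Every vection onset and offset is mirrored by a
#' button event (buttons are direction-specific).
#'
#' Session time: main trial `k` starts after `k - 1` full trials; each
#' trial is jitter + rotation + post-rotation. Practice trials precede the
#' recording and carry no session times.
#'
#' @param design An [experiment_design()].
#' @param profile A [subject_profile()].
#' @param seed Optional integer seed.
#' @return A data frame of class `trial_table`, one row per trial with
#'   columns `trial`, `is_practice`, `main_index`, `block`, `condition`,
#'   `direction`, `motion_onset_s`, `motion_offset_s`, `vection_present`,
#'   `vection_onset_s`, `vection_offset_s` (seconds relative to motion
#'   onset, `NA` when absent) and `strength`. Button events are attached
#'   as attribute `"buttons"` (a data frame: `time_s`, `button`, `trial`)
#'   and retrievable with [button_events()].
#' @export
generate_behaviour <- function(design = experiment_design(),
                               profile = subject_profile(),
                               seed = NULL) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(profile, "subject_profile"))
  if (!is.null(seed)) set.seed(seed)

  main_cond <- c(rep("coherent", design$n_coherent),
                 rep("incoherent", design$n_incoherent))
  main_dir <- c(rep(c("CW", "CCW"), each = design$n_per_direction),
                rep(c("CW", "CCW"), each = design$n_incoherent %/% 2L))
  ord <- block_randomize(length(main_cond), design$block_size)

  n_prac <- design$practice_trials
  prac_cond <- rep(c("coherent", "incoherent"), each = n_prac %/% 2L)
  prac_dir <- rep(rep(c("CW", "CCW"), each = max(1L, n_prac %/% 4L)),
                  length.out = n_prac)
  prac_ord <- if (n_prac > 0L) sample.int(n_prac) else integer(0)

  trials <- data.frame(
    trial = seq_len(n_prac + length(main_cond)),
    is_practice = c(rep(TRUE, n_prac), rep(FALSE, length(main_cond))),
    main_index = c(rep(NA_integer_, n_prac), seq_along(main_cond)),
    block = c(rep(0L, n_prac),
              (seq_along(main_cond) - 1L) %/% design$block_size + 1L),
    condition = c(prac_cond[prac_ord], main_cond[ord]),
    direction = c(prac_dir[prac_ord], main_dir[ord]),
    stringsAsFactors = FALSE
  )

  n_all <- nrow(trials)
  jitter <- stats::runif(n_all, design$pre_jitter_range[1],
                         design$pre_jitter_range[2])
  trial_len <- jitter + design$rotation_duration + design$post_duration
  # session clock runs over main trials only (EEG starts after practice)
  main_rows <- which(!trials$is_practice)
  starts <- cumsum(c(0, trial_len[main_rows]))[seq_along(main_rows)]
  trials$motion_onset_s <- NA_real_
  trials$motion_onset_s[main_rows] <- starts + jitter[main_rows]
  trials$motion_offset_s <- trials$motion_onset_s + design$rotation_duration

  p <- profile$presence_prob[trials$condition]
  trials$vection_present <- stats::runif(n_all) < p

  onset <- rlnorm_trunc(n_all,
                        profile$onset_meanlog[trials$condition],
                        profile$onset_sdlog[trials$condition],
                        upper = design$rotation_duration - 0.5)
  dur <- stats::rlnorm(n_all,
                       profile$duration_meanlog[trials$condition],
                       profile$duration_sdlog[trials$condition])
  offset <- pmin(onset + dur, design$rotation_duration)

  trials$vection_onset_s <- ifelse(trials$vection_present, onset, NA_real_)
  trials$vection_offset_s <- ifelse(trials$vection_present, offset, NA_real_)

  drift <- profile$habituation_slope *
    ifelse(trials$is_practice, 0, trials$main_index - 1L)
  raw <- stats::rnorm(n_all, profile$strength_mean[trials$condition] - drift,
                      profile$strength_sd)
  trials$strength <- ifelse(trials$vection_present,
                            pmin(10L, pmax(0L, as.integer(round(raw)))), 0L)

  rows <- which(trials$vection_present & !trials$is_practice)
  buttons <- data.frame(
    time_s = c(trials$motion_onset_s[rows] + trials$vection_onset_s[rows],
               trials$motion_onset_s[rows] + trials$vection_offset_s[rows]),
    button = c(paste0(trials$direction[rows], "_onset"),
               paste0(trials$direction[rows], "_offset")),
    trial = c(trials$trial[rows], trials$trial[rows]),
    stringsAsFactors = FALSE
  )
  buttons <- buttons[order(buttons$time_s), , drop = FALSE]
  rownames(buttons) <- NULL

  attr(trials, "buttons") <- buttons
  class(trials) <- c("trial_table", "data.frame")
  trials
}

#' Button events of a trial table
#'
#' @param trials A trial table from [generate_behaviour()].
#' @return Data frame with `time_s`, `button`, `trial`, sorted by time.
#' @export
button_events <- function(trials) {
  b <- attr(trials, "buttons")
  if (is.null(b)) {
    b <- data.frame(time_s = numeric(0), button = character(0),
                    trial = integer(0), stringsAsFactors = FALSE)
  }
  b
}

#' Main (non-practice) trials of a trial table
#'
#' @param trials A trial table.
#' @return The subset of rows with `is_practice == FALSE`, buttons kept.
#' @export
main_trials <- function(trials) {
  out <- trials[!trials$is_practice, , drop = FALSE]
  attr(out, "buttons") <- button_events(trials)
  class(out) <- class(trials)
  out
}

# Permute 1..n within consecutive blocks of `block` elements.
block_randomize <- function(n, block) {
  idx <- seq_len(n)
  split_id <- (idx - 1L) %/% block
  unlist(lapply(split(idx, split_id), sample), use.names = FALSE)
}

# Log-normal truncated to (0, upper] by resampling, falling back to the
# bound for stragglers.
rlnorm_trunc <- function(n, meanlog, sdlog, upper, max_tries = 20L) {
  x <- stats::rlnorm(n, meanlog, sdlog)
  for (k in seq_len(max_tries)) {
    bad <- which(x > upper)
    if (!length(bad)) break
    x[bad] <- stats::rlnorm(length(bad),
                            if (length(meanlog) > 1L) meanlog[bad] else meanlog,
                            if (length(sdlog) > 1L) sdlog[bad] else sdlog)
  }
  pmin(x, upper)
}
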