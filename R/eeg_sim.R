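#' Generate a continuous multichannel EEG session
#'
#' Synthesizes the EEG of one session as the sum of (a) per-channel 1/f
#' background noise with the profile's spectral exponent, (b) an alpha
#' oscillation at the profile's individual peak frequency with random
#' phase per trial and channel, whose power at the profile's ROI
#' electrodes is reduced by `coherent_alpha_drop` throughout coherent
#' rotation periods and additionally modulated around each reported
#' vection onset (a pre-onset dip and a sustained rise during ongoing
#' vection, in decibels), (c) theta (5 Hz) and beta (25 Hz) oscillations
#' with no condition dependence, and (d) optional square-pulse button
#' artifacts at button-event times. Event markers are placed at the exact
#' samples of motion on/off and vection on/off.
#'
#' With `coherent_alpha_drop = 0` and zero onset-locked parameters the
#' generator is a null model: coherent and incoherent rotation periods are
#' statistically exchangeable at every channel.
#'
#' @param design An [experiment_design()].
#' @param profile A [subject_profile()].
#' @param montage An `electrode_montage`.
#' @param trials Trial table from [generate_behaviour()] (practice rows
#'   are ignored; the session covers the main trials).
#' @param seed Optional integer seed.
#' @param button_artifact_uv Amplitude of the square button artifact in
#'   microvolts (0 disables). Default 150 so that the 100 muV rejection
#'   rule is exercised.
#' @param button_artifact_s Artifact duration in seconds.
#' @return An object of class `eeg_session`: `channel_labels`, `data`
#'   (channels x samples matrix, microvolts), `sampling_rate`, and
#'   `events` (data frame: `sample`, `code`, `trial` with codes
#'   `motion_on`, `motion_off`, `vection_on`, `vection_off`).
#' @export
generate_eeg_session <- function(design, profile, montage, trials,
                                 seed = NULL,
                                 button_artifact_uv = 150,
                                 button_artifact_s = 0.05) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(profile, "subject_profile"),
            inherits(montage, "electrode_montage"))
  if (!all(profile$roi_labels %in% montage$labels)) {
    stop("profile ROI labels missing from montage", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  tr <- trials[!trials$is_practice, , drop = FALSE]
  fs <- design$sampling_rate
  total_s <- max(tr$motion_offset_s) + design$post_duration
  n <- as.integer(round(total_s * fs))
  if (any(tr$motion_offset_s > total_s + 1e-9)) {
    stop("trial times exceed session length", call. = FALSE)
  }
  n_ch <- length(montage$labels)
  t <- (seq_len(n) - 1L) / fs

  # per-sample trial membership (trial k spans [end of k-1, end of k))
  trial_end <- tr$motion_offset_s + design$post_duration
  trial_of_sample <- findInterval(t, c(0, trial_end[-nrow(tr)]))

  samp <- function(x) pmin(n, pmax(1L, as.integer(round(x * fs)) + 1L))

  # alpha amplitude envelopes (shared across channels within/outside ROI)
  env_base <- rep(profile$alpha_amp_uv, n)
  env_roi <- env_base
  olp <- profile$onset_locked_params
  for (k in seq_len(nrow(tr))) {
    on_i <- samp(tr$motion_onset_s[k])
    off_i <- samp(tr$motion_offset_s[k])
    if (tr$condition[k] == "coherent") {
      env_roi[on_i:off_i] <- env_roi[on_i:off_i] *
        sqrt(1 - profile$coherent_alpha_drop)
      if (isTRUE(tr$vection_present[k])) {
        v_on <- tr$motion_onset_s[k] + tr$vection_onset_s[k]
        v_off <- tr$motion_onset_s[k] + tr$vection_offset_s[k]
        dip <- samp(c(v_on - olp[["dip_lead_s"]], v_on))
        env_roi[dip[1]:dip[2]] <- env_roi[dip[1]:dip[2]] *
          10^(olp[["dip_db"]] / 20)
        if (v_on + olp[["rise_lag_s"]] < v_off) {
          ris <- samp(c(v_on + olp[["rise_lag_s"]], v_off))
          env_roi[ris[1]:ris[2]] <- env_roi[ris[1]:ris[2]] *
            10^(olp[["rise_db"]] / 20)
        }
      }
    }
  }

  is_roi <- montage$labels %in% profile$roi_labels
  data <- matrix(0, nrow = n_ch, ncol = n)
  two_pi_t <- 2 * pi * t
  for (ch in seq_len(n_ch)) {
    bg <- pink_noise(n, fs, profile$aperiodic_exponent) * profile$noise_sd_uv
    ph_alpha <- stats::runif(nrow(tr) + 1L, 0, 2 * pi)[trial_of_sample]
    env <- if (is_roi[ch]) env_roi else env_base
    # slow stochastic amplitude modulation gives the alpha peak a
    # realistic spectral width (~1-2 Hz) instead of a one-bin line;
    # normalized so the mean alpha power is untouched
    am <- pmax(0, 1 + 0.5 * lowpass_noise(n, fs, 0.75))
    am <- am / sqrt(mean(am^2))
    alpha <- env * am * sin(two_pi_t * profile$alpha_peak_hz + ph_alpha)
    theta <- 2 * sin(two_pi_t * 5 + stats::runif(1, 0, 2 * pi))
    beta <- 1 * sin(two_pi_t * 25 + stats::runif(1, 0, 2 * pi))
    data[ch, ] <- bg + alpha + theta + beta
  }

  if (button_artifact_uv > 0) {
    b <- button_events(trials)
    b <- b[b$trial %in% tr$trial, , drop = FALSE]
    w <- max(1L, as.integer(round(button_artifact_s * fs)))
    for (bt in b$time_s) {
      i0 <- samp(bt)
      idx <- i0:min(n, i0 + w - 1L)
      data[, idx] <- data[, idx] + button_artifact_uv
    }
  }

  ev <- list(data.frame(sample = samp(tr$motion_onset_s), code = "motion_on",
                        trial = tr$trial),
             data.frame(sample = samp(tr$motion_offset_s), code = "motion_off",
                        trial = tr$trial))
  vp <- which(tr$vection_present)
  if (length(vp)) {
    ev <- c(ev, list(
      data.frame(sample = samp(tr$motion_onset_s[vp] + tr$vection_onset_s[vp]),
                 code = "vection_on", trial = tr$trial[vp]),
      data.frame(sample = samp(tr$motion_onset_s[vp] + tr$vection_offset_s[vp]),
                 code = "vection_off", trial = tr$trial[vp])))
  }
  events <- do.call(rbind, ev)
  events <- events[order(events$sample), , drop = FALSE]
  rownames(events) <- NULL

  structure(
    list(channel_labels = montage$labels,
         data = data,
         sampling_rate = fs,
         events = events),
    class = "eeg_session"
  )
}

#' @export
print.eeg_session <- function(x, ...) {
  cat(sprintf("<eeg_session> %d channels x %d samples @ %.0f Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate, nrow(x$events)))
  invisible(x)
}

# 1/f^exponent background noise (power spectrum), unit variance.
# White Gaussian noise is shaped in the frequency domain: amplitude
# scaled by f^(-exponent/2) for f > 0, DC removed.
# unit-variance Gaussian noise low-passed below `cutoff_hz`
lowpass_noise <- function(n, fs, cutoff_hz) {
  m <- stats::nextn(n, c(2, 3, 5))
  x <- stats::rnorm(m)
  xf <- stats::fft(x)
  f <- seq(0, fs, length.out = m + 1L)[seq_len(m)]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  xf[f > cutoff_hz] <- 0
  y <- Re(stats::fft(xf, inverse = TRUE))[seq_len(n)] / m
  y / stats::sd(y)
}

pink_noise <- function(n, fs, exponent) {
  m <- stats::nextn(n, c(2, 3, 5))  # composite FFT length, then truncate
  x <- stats::rnorm(m)
  xf <- stats::fft(x)
  f <- seq(0, fs, length.out = m + 1L)[seq_len(m)]
  f[f > fs / 2] <- fs - f[f > fs / 2]  # mirror to physical frequencies
  g <- c(0, f[-1L]^(-exponent / 2))
  y <- Re(stats::fft(xf * g, inverse = TRUE))[seq_len(n)] / m
  y / stats::sd(y)
}

#' Repair button artifacts by linear interpolation
#'
#' Replaces each button-pulse window (pulse duration plus a small guard
#' on both sides) with a per-channel linear interpolation between the
#' flanking samples. This is the package's minimal stand-in for the
#' artifact-cleaning stage of a real preprocessing pipeline: on synthetic
#' sessions the square button pulse is the only modelled artifact and its
#' timing is known exactly.
#'
#' @param eeg An `eeg_session`.
#' @param buttons Button events ([button_events()] data frame or numeric
#'   seconds).
#' @param width_s Pulse duration in seconds (default 0.05).
#' @param guard_s Extra guard interval on each side (default 0.01).
#' @return The repaired `eeg_session`.
#' @export
repair_button_artifacts <- function(eeg, buttons, width_s = 0.05,
                                    guard_s = 0.01) {
  stopifnot(inherits(eeg, "eeg_session"))
  if (is.data.frame(buttons)) buttons <- buttons$time_s
  if (!length(buttons)) return(eeg)
  fs <- eeg$sampling_rate
  n <- ncol(eeg$data)
  half_guard <- as.integer(round(guard_s * fs))
  w <- as.integer(round(width_s * fs))
  for (bt in buttons) {
    i0 <- max(2L, as.integer(round(bt * fs)) + 1L - half_guard)
    i1 <- min(n - 1L, i0 + w + 2L * half_guard)
    span <- i1 - i0 + 2L
    ramp <- seq_len(i1 - i0 + 1L) / span
    left <- eeg$data[, i0 - 1L]
    right <- eeg$data[, i1 + 1L]
    eeg$data[, i0:i1] <- left + outer(right - left, ramp)
  }
  eeg
}

#' Generate a cohort of synthetic subjects
#'
#' Draws `n_per_group` subjects per handedness group with independent
#' per-subject seeds derived from the master seed, left-handed profiles
#' carrying the left ROI and right-handed profiles the midline ROI by
#' default.
#'
#' @param n_per_group Subjects per handedness group (>= 1).
#' @param design An [experiment_design()].
#' @param montage An `electrode_montage`.
#' @param group_profiles Named list `list(left = , right = )` of
#'   [subject_profile()] templates; defaults to the standard profiles.
#' @param seed Master seed (integer).
#' @param eeg If `FALSE`, skip EEG synthesis (behaviour only; much
#'   faster).
#' @return List of subjects; each element has `id`, `group`, `profile`,
#'   `trials` and (if requested) `eeg`.
#' @export
generate_cohort <- function(n_per_group, design = experiment_design(),
                            montage = build_standard_montage(),
                            group_profiles = list(
                              left = subject_profile("left"),
                              right = subject_profile("right")),
                            seed = 1L, eeg = TRUE) {
  stopifnot(n_per_group >= 1,
            all(c("left", "right") %in% names(group_profiles)))
  subjects <- vector("list", 2L * n_per_group)
  i <- 0L
  for (grp in c("left", "right")) {
    for (k in seq_len(n_per_group)) {
      i <- i + 1L
      s_i <- subject_seed(seed, i)
      trials <- generate_behaviour(design, group_profiles[[grp]], seed = s_i)
      subj <- list(id = sprintf("%s%02d", substr(grp, 1, 1), k),
                   group = grp,
                   profile = group_profiles[[grp]],
                   trials = trials)
      if (eeg) {
        subj$eeg <- generate_eeg_session(design, group_profiles[[grp]],
                                         montage, trials, seed = s_i + 1L)
      }
      subjects[[i]] <- subj
    }
  }
  subjects
}

# Deterministic per-subject seed derivation, kept inside 32-bit range.
subject_seed <- function(master, index) {
  as.integer((as.numeric(master) * 1009 + 7919 * as.numeric(index)) %%
               2147483629) + 1L
}

#' Simulate subject-by-electrode alpha peak-power matrices
#'
#' Statistic-level counterpart of the full EEG generator, used for
#' resampling studies of the spatial cluster test at scales where
#' synthesizing raw EEG would be wasteful. Each subject has a log10
#' baseline alpha power (between-subject spread `between_sd`), each
#' condition/electrode measurement adds within-subject log10 noise
#' `within_sd`, and the coherent condition is attenuated by `drop` at the
#' `roi` electrodes.
#'
#' @param n_subjects Number of subjects.
#' @param montage An `electrode_montage`.
#' @param roi Electrode labels carrying the effect.
#' @param drop Fractional coherent-condition power decrease at `roi`
#'   (0 = null model).
#' @param base_log10_power Mean log10 alpha power (muV^2).
#' @param between_sd,within_sd Log10-unit standard deviations.
#' @param seed Optional integer seed.
#' @return List with matrices `coherent` and `incoherent`
#'   (`n_subjects x n_channels`, linear power, electrode dimnames).
#' @export
simulate_peak_power_cohort <- function(n_subjects = 25,
                                       montage = build_standard_montage(),
                                       roi = roi_electrodes("left"),
                                       drop = 0.3,
                                       base_log10_power = 0.5,
                                       between_sd = 0.3,
                                       within_sd = 0.08,
                                       seed = NULL) {
  stopifnot(n_subjects >= 2, drop >= 0, drop < 1,
            all(roi %in% montage$labels))
  if (!is.null(seed)) set.seed(seed)
  n_ch <- length(montage$labels)
  base <- stats::rnorm(n_subjects, base_log10_power, between_sd)
  noise <- function() matrix(stats::rnorm(n_subjects * n_ch, 0, within_sd),
                             n_subjects, n_ch)
  incoh <- 10^(base + noise())
  coh <- 10^(base + noise())
  coh[, montage$labels %in% roi] <- coh[, montage$labels %in% roi] * (1 - drop)
  dimnames(coh) <- dimnames(incoh) <- list(NULL, montage$labels)
  list(coherent = coh, incoherent = incoh)
}

#' Simulate ROI alpha time-courses locked to vection onset
#'
#' Statistic-level generator for the temporal cluster test: per subject, a
#' decibel alpha time-course over the -3..+5 s epoch with temporally
#' smoothed noise, a `dip_db` deviation over `dip_window` and a sustained
#' `rise_db` deviation from `rise_start_s` to the epoch end (0 dB
#' elsewhere, i.e. at baseline).
#'
#' @param n_subjects Number of subjects.
#' @param fs Time-grid resolution in Hz.
#' @param dip_db,dip_window Pre-onset dip depth (dB) and window (s).
#' @param rise_db,rise_start_s Ongoing-vection rise (dB) and start (s).
#' @param noise_sd Per-timepoint noise SD after smoothing, dB.
#' @param smooth_s Moving-average width of the noise, seconds.
#' @param seed Optional integer seed.
#' @return List with `times` (s, -3..+5), `values` (n_subjects x
#'   n_times dB matrix), and the windows used.
#' @export
simulate_roi_trace_cohort <- function(n_subjects = 25,
                                      fs = 100,
                                      dip_db = -1.5,
                                      dip_window = c(-0.5, 0),
                                      rise_db = 1.0,
                                      rise_start_s = 1.5,
                                      noise_sd = 0.8,
                                      smooth_s = 0.2,
                                      seed = NULL) {
  stopifnot(n_subjects >= 2, fs > 0, noise_sd > 0)
  if (!is.null(seed)) set.seed(seed)
  times <- seq(-3, 5, by = 1 / fs)
  nt <- length(times)
  shape <- numeric(nt)
  shape[times >= dip_window[1] & times <= dip_window[2]] <- dip_db
  shape[times >= rise_start_s] <- rise_db
  w <- max(1L, as.integer(round(smooth_s * fs)))
  kern <- rep(1 / w, w)
  values <- matrix(0, n_subjects, nt)
  for (s in seq_len(n_subjects)) {
    eps <- stats::rnorm(nt + w)
    sm <- stats::filter(eps, kern, sides = 2)
    sm <- sm[!is.na(sm)][seq_len(nt)]
    values[s, ] <- shape + noise_sd * sm / stats::sd(sm)
  }
  list(times = times, values = values,
       dip_window = dip_window, rise_start_s = rise_start_s)
}
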