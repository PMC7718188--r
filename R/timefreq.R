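#' Select trials eligible for onset-locked analysis
#'
#' Keeps coherent, vection-present trials with (a) at least `min_pre_s`
#' seconds between motion onset and vection onset and (b) at least
#' `min_ongoing_s` seconds of continual ongoing vection after onset.
#' Exclusion reasons are attached as `attr(, "log")`.
#'
#' @param trials A trial table.
#' @param min_pre_s Minimum onset latency (default 3).
#' @param min_ongoing_s Minimum vection duration after onset (default 5).
#' @return The eligible subset of `trials`.
#' @export
select_eligible_trials <- function(trials, min_pre_s = 3,
                                   min_ongoing_s = 5) {
  tr <- trials[!trials$is_practice & trials$condition == "coherent", ,
               drop = FALSE]
  reason <- rep(NA_character_, nrow(tr))
  reason[!tr$vection_present] <- "no_vection"
  lat <- tr$vection_onset_s
  dur <- tr$vection_offset_s - tr$vection_onset_s
  reason[is.na(reason) & lat < min_pre_s] <- "onset_too_early"
  reason[is.na(reason) & dur < min_ongoing_s] <- "vection_too_short"
  out <- tr[is.na(reason), , drop = FALSE]
  attr(out, "log") <- data.frame(trial = tr$trial[!is.na(reason)],
                                 reason = reason[!is.na(reason)],
                                 stringsAsFactors = FALSE)
  class(out) <- class(trials)
  out
}

#' Extract vection-onset-locked epochs
#'
#' Cuts one epoch per eligible trial, from `pre_s` seconds before to
#' `post_s` seconds after vection onset (time 0 = vection onset; the
#' default -3..+5 s span gives exactly `8 * sampling_rate` samples).
#' Trials whose span leaves the recorded data are dropped and logged.
#'
#' @param eeg An `eeg_session`.
#' @param trials Eligible trials from [select_eligible_trials()].
#' @param pre_s,post_s Seconds before/after vection onset.
#' @param channels Optional subset of channel labels to keep (e.g. an
#'   ROI), saving memory.
#' @return A list of class `onset_epochs`; each element is an
#'   `eeg_epoch` (`data`: channels x samples, `times`, `sampling_rate`,
#'   `channel_labels`, `trial`). Dropped trials in `attr(, "log")`.
#' @export
extract_onset_epochs <- function(eeg, trials, pre_s = 3, post_s = 5,
                                 channels = NULL) {
  stopifnot(inherits(eeg, "eeg_session"), pre_s > 0, post_s > 0)
  fs <- eeg$sampling_rate
  n_samp <- as.integer(round((pre_s + post_s) * fs))
  times <- seq(-pre_s, by = 1 / fs, length.out = n_samp)
  ch_idx <- if (is.null(channels)) {
    seq_along(eeg$channel_labels)
  } else {
    idx <- match(channels, eeg$channel_labels)
    if (anyNA(idx)) stop("unknown channels requested", call. = FALSE)
    idx
  }
  epochs <- list()
  dropped <- list()
  for (k in seq_len(nrow(trials))) {
    t0 <- trials$motion_onset_s[k] + trials$vection_onset_s[k]
    start <- as.integer(round((t0 - pre_s) * fs)) + 1L
    stop_ <- start + n_samp - 1L
    if (start < 1L || stop_ > ncol(eeg$data)) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(trial = trials$trial[k], reason = "outside_recording")
      next
    }
    epochs[[length(epochs) + 1L]] <- structure(
      list(data = eeg$data[ch_idx, start:stop_, drop = FALSE],
           times = times,
           sampling_rate = fs,
           channel_labels = eeg$channel_labels[ch_idx],
           trial = trials$trial[k]),
      class = "eeg_epoch"
    )
  }
  structure(epochs, class = "onset_epochs",
            log = if (length(dropped)) do.call(rbind, dropped) else NULL)
}

#' Morlet wavelet time-frequency decomposition
#'
#' Convolves each channel with complex Morlet wavelets (Gaussian-envelope
#' analytic filters implemented in the frequency domain, peak gain 1 at
#' the center frequency) and returns linear power. The epoch is padded by
#' reflection before convolution; the edge-contaminated margin of half a
#' wavelet length (`cycles / 2 / f` seconds) per side is reported per
#' frequency in `margins_s`.
#'
#' @param epoch An `eeg_epoch` (or a list with `data`, `times`,
#'   `sampling_rate`, `channel_labels`).
#' @param freqs Analysis frequencies in Hz (default 3-40 in 1 Hz steps).
#' @param cycles Wavelet width in cycles (default 7).
#' @return An object of class `tf_map`: `power` is a
#'   frequencies x times x channels array (linear units),
#'   `normalized = FALSE`, plus `freqs`, `times`, `wavelet_cycles`,
#'   `channel_labels`, `margins_s`.
#' @export
morlet_tf <- function(epoch, freqs = 3:40, cycles = 7) {
  fs <- epoch$sampling_rate
  if (any(freqs <= 0) || any(freqs >= fs / 2)) {
    stop("analysis frequencies must lie in (0, Nyquist)", call. = FALSE)
  }
  x <- epoch$data
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  ns <- ncol(x)
  n_ch <- nrow(x)

  pad <- min(ns - 1L, as.integer(ceiling(cycles / 2 / min(freqs) * fs)))
  xp <- cbind(x[, pad:1, drop = FALSE], x,
              x[, ns:(ns - pad + 1L), drop = FALSE])
  np <- ncol(xp)
  xf <- stats::mvfft(t(xp))                       # np x channels
  fgrid <- (seq_len(np) - 1L) / np * fs           # 0 .. fs
  positive <- fgrid > 0 & fgrid <= fs / 2

  power <- array(NA_real_, dim = c(length(freqs), ns, n_ch))
  keep <- pad + seq_len(ns)
  for (j in seq_along(freqs)) {
    f0 <- freqs[j]
    sigma_t <- cycles / (2 * pi * f0)
    h <- numeric(np)
    h[positive] <- 2 * exp(-((fgrid[positive] - f0) * 2 * pi * sigma_t)^2 / 2)
    analytic <- stats::mvfft(xf * h, inverse = TRUE) / np
    power[j, , ] <- Mod(analytic[keep, , drop = FALSE])^2
  }

  structure(
    list(freqs = as.numeric(freqs),
         times = epoch$times,
         power = power,
         normalized = FALSE,
         wavelet_cycles = cycles,
         channel_labels = epoch$channel_labels,
         margins_s = cycles / 2 / as.numeric(freqs)),
    class = "tf_map"
  )
}

#' Average time-frequency maps across trials
#'
#' Linear power is averaged element-wise; all maps must share grids and
#' must not yet be normalized (per-subject decibel conversion comes after
#' trial averaging).
#'
#' @param tfmaps List of `tf_map`s.
#' @return A single `tf_map` carrying `n_trials`.
#' @export
tf_average <- function(tfmaps) {
  stopifnot(length(tfmaps) >= 1)
  if (any(vapply(tfmaps, `[[`, TRUE, "normalized"))) {
    stop("average linear power before decibel normalization", call. = FALSE)
  }
  out <- tfmaps[[1L]]
  if (length(tfmaps) > 1L) {
    acc <- out$power
    for (m in tfmaps[-1L]) acc <- acc + m$power
    out$power <- acc / length(tfmaps)
  }
  out$n_trials <- length(tfmaps)
  out
}

#' Decibel baseline normalization of a time-frequency map
#'
#' Per frequency and channel, power is converted to
#' `10 * log10(power / mean power over the normalization interval)`.
#' A map can only be normalized once; re-normalizing raises an error.
#'
#' @param tfmap A `tf_map` with linear power.
#' @param norm_interval Normalization interval in seconds, half-open
#'   `[a, b)`; default (-2.5, -1.5) relative to vection onset.
#' @return The normalized `tf_map` (`normalized = TRUE`, values in dB).
#' @export
db_normalize <- function(tfmap, norm_interval = c(-2.5, -1.5)) {
  stopifnot(inherits(tfmap, "tf_map"))
  if (isTRUE(tfmap$normalized)) {
    stop("tf_map is already decibel-normalized", call. = FALSE)
  }
  sel <- tfmap$times >= norm_interval[1] & tfmap$times < norm_interval[2]
  if (!any(sel)) stop("normalization interval outside epoch", call. = FALSE)
  base <- apply(tfmap$power[, sel, , drop = FALSE], c(1, 3), mean)
  if (any(!is.finite(base)) || any(base <= 0)) {
    stop("baseline power is zero or non-finite; cannot normalize",
         call. = FALSE)
  }
  for (ch in seq_len(dim(tfmap$power)[3])) {
    tfmap$power[, , ch] <- 10 * log10(tfmap$power[, , ch] / base[, ch])
  }
  tfmap$normalized <- TRUE
  tfmap$norm_interval <- norm_interval
  tfmap
}

#' ROI alpha-band time-course from a normalized TF map
#'
#' Averages decibel power over the ROI channels and the alpha-band
#' frequencies, then derives the scalar baseline (mean over the baseline
#' window, one value per participant) and the ongoing-vection trace.
#' Windows are half-open `[a, b)`: baseline -1.5..-0.5 s and vection
#' window -0.5..+4 s by default.
#'
#' @param tfmap A normalized `tf_map` containing the ROI channels.
#' @param roi_labels ROI electrode labels.
#' @param band Frequency band in Hz (default 7-14, inclusive).
#' @param baseline_window,vection_window Analysis windows in seconds.
#' @param decimate_by Integer subsampling factor applied to the time grid
#'   (1 = keep the full grid). The grid actually used is recorded in the
#'   result.
#' @return An object of class `roi_timecourse`: full `times`/`values`
#'   (dB), `baseline_mean`, `vection_times`/`vection_values`, the
#'   windows, `roi_labels`, `band`, and `grid_hz`.
#' @export
roi_alpha_timecourse <- function(tfmap, roi_labels, band = c(7, 14),
                                 baseline_window = c(-1.5, -0.5),
                                 vection_window = c(-0.5, 4),
                                 decimate_by = 1L) {
  stopifnot(inherits(tfmap, "tf_map"), decimate_by >= 1)
  if (!isTRUE(tfmap$normalized)) {
    stop("normalize the tf_map before extracting ROI time-courses",
         call. = FALSE)
  }
  if (length(roi_labels) == 0L) stop("empty ROI", call. = FALSE)
  ch <- match(roi_labels, tfmap$channel_labels)
  if (anyNA(ch)) {
    stop("ROI labels missing from tf_map: ",
         paste(roi_labels[is.na(ch)], collapse = ", "), call. = FALSE)
  }
  fr <- which(tfmap$freqs >= band[1] & tfmap$freqs <= band[2])
  if (!length(fr)) stop("no analysis frequencies inside band", call. = FALSE)

  vals <- apply(tfmap$power[fr, , ch, drop = FALSE], 2, mean)
  times <- tfmap$times
  if (decimate_by > 1L) {
    idx <- seq(1L, length(times), by = as.integer(decimate_by))
    times <- times[idx]
    vals <- vals[idx]
  }
  bsel <- times >= baseline_window[1] & times < baseline_window[2]
  vsel <- times >= vection_window[1] & times < vection_window[2]

  structure(
    list(times = times, values = vals,
         baseline_mean = mean(vals[bsel]),
         vection_times = times[vsel],
         vection_values = vals[vsel],
         baseline_window = baseline_window,
         vection_window = vection_window,
         roi_labels = roi_labels, band = band,
         grid_hz = 1 / (times[2] - times[1])),
    class = "roi_timecourse"
  )
}

#' Per-subject onset-locked ROI alpha time-course
#'
#' Convenience pipeline for one subject: eligibility filter, epoch
#' extraction restricted to the ROI channels, per-trial Morlet transform,
#' trial-averaging of linear power, decibel normalization, and ROI/band
#' averaging.
#'
#' @param eeg An `eeg_session`.
#' @param trials The subject's trial table.
#' @param roi_labels ROI electrode labels.
#' @param freqs,cycles Morlet parameters.
#' @param decimate_by Time-grid subsampling factor for the returned
#'   trace.
#' @param repair_buttons If `TRUE` (default), button-pulse windows are
#'   repaired with [repair_button_artifacts()] before epoching (the
#'   onset button push otherwise contaminates the epoch at time 0).
#' @return A `roi_timecourse`, or `NULL` when no trial is eligible.
#' @export
subject_roi_timecourse <- function(eeg, trials, roi_labels,
                                   freqs = 3:40, cycles = 7,
                                   decimate_by = 1L,
                                   repair_buttons = TRUE) {
  eligible <- select_eligible_trials(trials)
  if (nrow(eligible) == 0L) return(NULL)
  if (repair_buttons) {
    eeg <- repair_button_artifacts(eeg, button_events(trials))
  }
  epochs <- extract_onset_epochs(eeg, eligible, channels = roi_labels)
  if (length(epochs) == 0L) return(NULL)
  maps <- lapply(epochs, morlet_tf, freqs = freqs, cycles = cycles)
  avg <- db_normalize(tf_average(maps))
  roi_alpha_timecourse(avg, roi_labels, decimate_by = decimate_by)
}
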