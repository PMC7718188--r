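#' Cut rotation periods into non-overlapping 1-second segments
#'
#' For every main trial of the requested condition, the period between the
#' `motion_on` and `motion_off` markers is cut into contiguous
#' non-overlapping 1-s segments (sample spans are half-open
#' `[start, end)`). CW and CCW trials are pooled. Trials with a missing
#' offset marker or a rotation period shorter than one segment are
#' skipped and recorded in the attached log.
#'
#' @param eeg An `eeg_session`.
#' @param trials The session's trial table.
#' @param condition `"coherent"` or `"incoherent"`.
#' @return Data frame with columns `trial`, `segment`, `start_sample`,
#'   `end_sample` (end exclusive); skipped trials are listed in
#'   `attr(, "log")`.
#' @export
segment_rotation_periods <- function(eeg, trials, condition) {
  stopifnot(inherits(eeg, "eeg_session"))
  fs <- eeg$sampling_rate
  seg_len <- as.integer(round(fs))
  tr <- trials[!trials$is_practice & trials$condition == condition, ,
               drop = FALSE]
  ev <- eeg$events
  out <- list()
  log <- list()
  for (k in seq_len(nrow(tr))) {
    id <- tr$trial[k]
    on <- ev$sample[ev$code == "motion_on" & ev$trial == id]
    off <- ev$sample[ev$code == "motion_off" & ev$trial == id]
    if (length(on) != 1L || length(off) != 1L) {
      warning("trial ", id, ": missing motion marker; skipped",
              call. = FALSE)
      log[[length(log) + 1L]] <- data.frame(trial = id,
                                            reason = "missing_marker")
      next
    }
    n_seg <- (off - on) %/% seg_len
    if (n_seg < 1L) {
      log[[length(log) + 1L]] <- data.frame(trial = id,
                                            reason = "rotation_too_short")
      next
    }
    starts <- on + (seq_len(n_seg) - 1L) * seg_len
    out[[length(out) + 1L]] <- data.frame(trial = id,
                                          segment = seq_len(n_seg),
                                          start_sample = starts,
                                          end_sample = starts + seg_len)
  }
  segs <- if (length(out)) do.call(rbind, out) else {
    data.frame(trial = integer(0), segment = integer(0),
               start_sample = integer(0), end_sample = integer(0))
  }
  rownames(segs) <- NULL
  attr(segs, "log") <- if (length(log)) do.call(rbind, log) else NULL
  segs
}

#' Reject artifact-contaminated segments
#'
#' A segment is dropped iff a button event falls inside its half-open
#' sample span or any channel sample within it exceeds `threshold_uv` in
#' absolute value. The rejection log (counts per reason) is attached as
#' `attr(, "rejection_log")`.
#'
#' @param eeg An `eeg_session`.
#' @param segments Segment table from [segment_rotation_periods()].
#' @param buttons Button events: a data frame with a `time_s` column (as
#'   returned by [button_events()]) or a numeric vector of seconds.
#' @param threshold_uv Absolute amplitude threshold in microvolts
#'   (default 100).
#' @return The kept subset of `segments` with the rejection log attached.
#' @export
reject_segments <- function(eeg, segments, buttons = NULL,
                            threshold_uv = 100) {
  stopifnot(inherits(eeg, "eeg_session"), threshold_uv > 0)
  if (is.data.frame(buttons)) buttons <- buttons$time_s
  btn_samples <- if (length(buttons)) {
    as.integer(round(buttons * eeg$sampling_rate)) + 1L
  } else integer(0)

  n <- nrow(segments)
  has_button <- logical(n)
  over_amp <- logical(n)
  for (k in seq_len(n)) {
    a <- segments$start_sample[k]
    b <- segments$end_sample[k]
    has_button[k] <- any(btn_samples >= a & btn_samples < b)
    over_amp[k] <- max(abs(eeg$data[, a:(b - 1L), drop = FALSE])) >
      threshold_uv
  }
  keep <- !(has_button | over_amp)
  out <- segments[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejection_log") <- list(
    n_total = n,
    n_button = sum(has_button),
    n_amplitude = sum(over_amp & !has_button),
    n_kept = sum(keep),
    threshold_uv = threshold_uv
  )
  out
}

#' Hann-windowed FFT amplitude spectrum, averaged over segments
#'
#' Each segment is multiplied with a Hann window and Fourier transformed;
#' single-sided amplitude spectra (scaled so that a sinusoid of amplitude
#' A at a bin frequency yields A at that bin) are averaged across
#' segments per channel. One-second segments give 1 Hz resolution.
#'
#' @param eeg An `eeg_session`.
#' @param segments Segment table (all segments must share one length).
#' @return An object of class `eeg_spectrum`: `freqs` (Hz),
#'   `amplitude` (channels x frequencies, microvolts), `n_segments`,
#'   `channel_labels`.
#' @export
compute_spectrum <- function(eeg, segments) {
  stopifnot(inherits(eeg, "eeg_session"))
  if (nrow(segments) == 0L) {
    stop("no segments left to average; review the rejection threshold",
         call. = FALSE)
  }
  lens <- unique(segments$end_sample - segments$start_sample)
  if (length(lens) != 1L) stop("segments have unequal lengths", call. = FALSE)
  nseg_len <- lens
  w <- hann_window(nseg_len)
  n_bins <- nseg_len %/% 2L + 1L
  scale <- c(1, rep(2, n_bins - 1L)) / sum(w)
  if (nseg_len %% 2L == 0L) scale[n_bins] <- 1 / sum(w)

  acc <- matrix(0, nrow(eeg$data), n_bins)
  for (k in seq_len(nrow(segments))) {
    seg <- t(eeg$data[, segments$start_sample[k]:(segments$end_sample[k] - 1L),
                      drop = FALSE]) * w
    sp <- stats::mvfft(seg)[seq_len(n_bins), , drop = FALSE]
    acc <- acc + t(abs(sp)) * rep(scale, each = nrow(acc))
  }
  amplitude <- acc / nrow(segments)
  freqs <- (seq_len(n_bins) - 1L) * eeg$sampling_rate / nseg_len
  structure(
    list(freqs = freqs, amplitude = amplitude,
         n_segments = nrow(segments),
         channel_labels = eeg$channel_labels),
    class = "eeg_spectrum"
  )
}

# periodic Hann window: a sinusoid at an exact bin frequency stays
# leakage-free
hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)
}

#' Parameterize a spectrum as aperiodic 1/f background plus Gaussian peaks
#'
#' Fits `log10 power = offset - exponent * log10(f) + sum of Gaussians`
#' over the fit range by (i) a robust aperiodic fit that iteratively
#' down-weights peak regions, (ii) greedy extraction of Gaussians from
#' the flattened residual (largest residual maximum first, while it
#' exceeds both `peak_threshold_sd` residual standard deviations and
#' `min_peak_height`), (iii) pruning of overlapping candidates (the
#' taller peak wins when centers are closer than the pair's larger
#' bandwidth), and (iv) a joint box-constrained refit of all parameters.
#'
#' @param spectrum An `eeg_spectrum`.
#' @param channel Channel label or index.
#' @param fit_range_hz Frequency range of the fit, default 3-40 Hz.
#' @param max_peaks Maximum number of Gaussians (default 6).
#' @param peak_threshold_sd Relative peak threshold in residual SDs.
#' @param min_peak_height Absolute minimum peak height, log10-power units.
#' @return An object of class `spectral_fit`: `aperiodic_offset`,
#'   `aperiodic_exponent`, `peaks` (data frame `center_hz`, `height`,
#'   `bandwidth_hz`, sorted by height), `fit_range_hz`, `goodness`
#'   (residual RMSE).
#' @export
fit_spectral_model <- function(spectrum, channel, fit_range_hz = c(3, 40),
                               max_peaks = 6L, peak_threshold_sd = 2,
                               min_peak_height = 0.05) {
  stopifnot(inherits(spectrum, "eeg_spectrum"))
  ch <- if (is.character(channel)) {
    match(channel, spectrum$channel_labels)
  } else as.integer(channel)
  if (is.na(ch) || ch < 1L || ch > nrow(spectrum$amplitude)) {
    stop("unknown channel: ", channel, call. = FALSE)
  }
  sel <- spectrum$freqs >= fit_range_hz[1] & spectrum$freqs <= fit_range_hz[2] &
    spectrum$freqs > 0
  f <- spectrum$freqs[sel]
  pw <- spectrum$amplitude[ch, sel]^2
  if (!all(is.finite(pw)) || any(pw <= 0)) {
    stop("spectrum is not finite and positive over the fit range",
         call. = FALSE)
  }
  lp <- log10(pw)
  lf <- log10(f)

  # (i) robust aperiodic fit: refit on the points least contaminated by
  # peaks (peaks only push residuals upward)
  ap <- stats::coef(stats::lm(lp ~ lf))
  for (iter in 1:2) {
    resid <- lp - (ap[1] + ap[2] * lf)
    keep <- resid <= stats::quantile(resid, 0.6)
    ap <- stats::coef(stats::lm(lp[keep] ~ lf[keep]))
  }
  flat <- lp - (ap[1] + ap[2] * lf)

  # (ii)-(iii) greedy Gaussian extraction
  peaks <- list()
  work <- flat
  for (k in seq_len(max_peaks)) {
    i0 <- which.max(work)
    h <- work[i0]
    if (h < max(peak_threshold_sd * stats::sd(work), min_peak_height)) break
    cf <- f[i0]
    half <- h / 2
    li <- i0; while (li > 1L && work[li] > half) li <- li - 1L
    ri <- i0; while (ri < length(work) && work[ri] > half) ri <- ri + 1L
    # shorter one-sided half-width: robust when a neighbouring peak
    # keeps the residual elevated on the other side
    hw <- max(min(cf - f[li], f[ri] - cf), f[2] - f[1])
    bw <- min(6, max(0.5, 2 * hw / 2.355))
    # refine by a local single-Gaussian least-squares fit; the raw
    # half-width guess is fragile when noise dips near the maximum
    win <- abs(f - cf) <= max(1.5 * bw, 2)
    loc <- stats::optim(
      c(cf, h, bw),
      function(q) sum((work[win] -
                         q[2] * exp(-(f[win] - q[1])^2 / (2 * q[3]^2)))^2),
      method = "L-BFGS-B",
      lower = c(cf - 1, h / 4, 0.3),
      upper = c(cf + 1, 2 * h, min(8, 2.5 * bw)))
    cf <- loc$par[1]; h <- loc$par[2]; bw <- loc$par[3]
    peaks[[k]] <- c(center = cf, height = h, bw = bw)
    work <- work - h * exp(-(f - cf)^2 / (2 * bw^2))
  }
  if (length(peaks)) {
    peaks <- prune_overlapping_peaks(do.call(rbind, peaks))
  }

  # (iv) joint refit
  if (length(peaks)) {
    p0 <- c(ap[1], -ap[2], as.vector(t(peaks)))
    npk <- nrow(peaks)
    lower <- c(-Inf, 0, rep(c(fit_range_hz[1], 1e-6, 0.3), npk))
    upper <- c(Inf, 5, rep(c(fit_range_hz[2], Inf, 8), npk))
    objective <- function(par) {
      model <- par[1] - par[2] * lf
      for (j in seq_len(npk)) {
        q <- par[2 + (j - 1) * 3 + 1:3]
        model <- model + q[2] * exp(-(f - q[1])^2 / (2 * q[3]^2))
      }
      sum((lp - model)^2)
    }
    fit <- stats::optim(p0, objective, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 500))
    par <- fit$par
    offset <- par[1]
    exponent <- par[2]
    pk <- matrix(par[-(1:2)], ncol = 3, byrow = TRUE)
    pk <- pk[pk[, 2] >= min_peak_height, , drop = FALSE]
    colnames(pk) <- c("center", "height", "bw")
    pk <- prune_overlapping_peaks(pk)
    resid_final <- sqrt(objective(par) / length(lp))
  } else {
    offset <- unname(ap[1])
    exponent <- unname(-ap[2])
    pk <- matrix(numeric(0), ncol = 3)
    resid_final <- sqrt(mean(flat^2))
  }

  peaks_df <- data.frame(center_hz = pk[, 1], height = pk[, 2],
                         bandwidth_hz = pk[, 3])
  peaks_df <- peaks_df[order(-peaks_df$height), , drop = FALSE]
  rownames(peaks_df) <- NULL

  structure(
    list(channel = spectrum$channel_labels[ch],
         aperiodic_offset = unname(offset),
         aperiodic_exponent = unname(exponent),
         peaks = peaks_df,
         fit_range_hz = fit_range_hz,
         goodness = resid_final),
    class = "spectral_fit"
  )
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("<spectral_fit> %s: offset %.2f, exponent %.2f, %d peak(s), rmse %.3f\n",
              x$channel, x$aperiodic_offset, x$aperiodic_exponent,
              nrow(x$peaks), x$goodness))
  if (nrow(x$peaks)) print(round(x$peaks, 2))
  invisible(x)
}

# Keep only peaks whose center is farther than the pair's larger
# bandwidth (Gaussian SD) from every taller kept peak; noise-induced
# satellites overlapping a real peak otherwise destabilize the refit.
prune_overlapping_peaks <- function(pk) {
  if (nrow(pk) <= 1L) return(pk)
  pk <- pk[order(-pk[, "height"]), , drop = FALSE]
  keep <- 1L
  for (j in 2:nrow(pk)) {
    sep <- abs(pk[keep, "center"] - pk[j, "center"])
    lim <- pmax(pk[keep, "bw"], pk[j, "bw"])
    if (all(sep > lim)) keep <- c(keep, j)
  }
  pk[keep, , drop = FALSE]
}

# canonical band edges; lower edge closed, upper edge open (beta closed)
band_edges <- function(band) {
  switch(band,
         theta = c(4, 7),
         alpha = c(7, 14),
         beta = c(20, 30),
         stop("unknown band: ", band, call. = FALSE))
}

#' Extract the individual band peak from a spectral fit
#'
#' Selects, among the fitted Gaussians whose center lies inside the band
#' (theta 4-7 Hz, alpha 7-14 Hz, beta 20-30 Hz; lower edge closed), the
#' one with the greatest height above the aperiodic component. The
#' reported `power_value` is the linear power of the raw spectrum at the
#' frequency bin nearest the peak center. When no fitted peak lies in the
#' band, `found` is `FALSE` and the maximum raw in-band power is reported
#' instead, so no electrode is silently dropped.
#'
#' @param fit A `spectral_fit`.
#' @param spectrum The `eeg_spectrum` the fit came from.
#' @param band `"theta"`, `"alpha"` or `"beta"`.
#' @return One-row data frame: `band`, `center_hz`, `power_value`,
#'   `found`.
#' @export
extract_band_peak <- function(fit, spectrum, band = c("alpha", "theta", "beta")) {
  band <- match.arg(band)
  stopifnot(inherits(fit, "spectral_fit"), inherits(spectrum, "eeg_spectrum"))
  edges <- band_edges(band)
  ch <- match(fit$channel, spectrum$channel_labels)
  pw <- spectrum$amplitude[ch, ]^2

  in_band <- fit$peaks$center_hz >= edges[1] &
    (fit$peaks$center_hz < edges[2] |
       (band == "beta" & fit$peaks$center_hz <= edges[2]))
  if (any(in_band)) {
    cand <- fit$peaks[in_band, , drop = FALSE]
    center <- cand$center_hz[which.max(cand$height)]
    bin <- which.min(abs(spectrum$freqs - center))
    data.frame(band = band, center_hz = center, power_value = pw[bin],
               found = TRUE, stringsAsFactors = FALSE)
  } else {
    bins <- which(spectrum$freqs >= edges[1] & spectrum$freqs <= edges[2])
    bin <- bins[which.max(pw[bins])]
    data.frame(band = band, center_hz = spectrum$freqs[bin],
               power_value = pw[bin], found = FALSE,
               stringsAsFactors = FALSE)
  }
}

#' Band peak power for every channel of a spectrum
#'
#' Convenience wrapper: fits the spectral model per channel and extracts
#' the requested band peak, returning one row per channel.
#'
#' @param spectrum An `eeg_spectrum`.
#' @param band Band name.
#' @param fit_range_hz Fit range passed to [fit_spectral_model()].
#' @return Data frame: `channel`, `band`, `center_hz`, `power_value`,
#'   `found`.
#' @export
band_peak_powers <- function(spectrum, band = "alpha",
                             fit_range_hz = c(3, 40)) {
  rows <- lapply(spectrum$channel_labels, function(ch) {
    fit <- fit_spectral_model(spectrum, ch, fit_range_hz)
    cbind(channel = ch, extract_band_peak(fit, spectrum, band))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
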