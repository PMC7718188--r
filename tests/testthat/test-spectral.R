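test_that("rotation periods are cut into twenty half-open 1-s segments", {
  fx <- fixture_session()
  segs <- segment_rotation_periods(fx$eeg, fx$trials, "coherent")
  expect_identical(nrow(segs), 10L * 20L)
  expect_true(all(table(segs$trial) == 20L))
  fs <- fx$eeg$sampling_rate
  expect_true(all(segs$end_sample - segs$start_sample == fs))
  # contiguous non-overlapping within a trial
  one <- segs[segs$trial == segs$trial[1], ]
  expect_identical(one$start_sample[-1], one$end_sample[-nrow(one)])
})

test_that("missing motion markers skip the trial with a warning", {
  fx <- fixture_session()
  eeg <- fx$eeg
  drop_trial <- main_trials(fx$trials)$trial[1]
  eeg$events <- eeg$events[!(eeg$events$code == "motion_off" &
                               eeg$events$trial == drop_trial), ]
  expect_warning(segs <- segment_rotation_periods(eeg, fx$trials, "coherent"),
                 "missing motion marker")
  expect_false(drop_trial %in% segs$trial)
  expect_identical(attr(segs, "log")$reason, "missing_marker")
})

test_that("segments with button pushes or over-threshold samples are rejected", {
  fs <- 100
  dat <- matrix(0, 2, 5 * fs)
  dat[2, 320] <- 150  # spike inside the 4th second
  eeg <- make_eeg(dat, fs)
  segs <- data.frame(trial = 1L, segment = 1:5,
                     start_sample = seq(1, 401, by = 100),
                     end_sample = seq(101, 501, by = 100))
  kept <- reject_segments(eeg, segs, buttons = 1.5, threshold_uv = 100)
  log <- attr(kept, "rejection_log")
  # segment 2 contains the button (1.5 s), segment 4 the amplitude spike
  expect_identical(kept$segment, c(1L, 3L, 5L))
  expect_identical(log$n_button, 1L)
  expect_identical(log$n_amplitude, 1L)

  # a button exactly on a boundary belongs to the following segment
  kept2 <- reject_segments(eeg, segs, buttons = 1.0, threshold_uv = 1000)
  expect_false(2L %in% kept2$segment)
  expect_true(1L %in% kept2$segment)

  # all-zero segments with no buttons are kept
  kept3 <- reject_segments(make_eeg(matrix(0, 2, 500), fs), segs)
  expect_identical(nrow(kept3), 5L)
})

test_that("the Hann FFT spectrum recovers sinusoid amplitude and frequency", {
  fs <- 250
  t <- (0:(10 * fs - 1)) / fs
  eeg <- make_eeg(sin(2 * pi * 10 * t), fs)
  segs <- data.frame(trial = 1L, segment = 1:10,
                     start_sample = seq(1, 10 * fs, by = fs),
                     end_sample = seq(fs + 1, 10 * fs + 1, by = fs))
  sp <- compute_spectrum(eeg, segs)
  expect_identical(sp$freqs[2] - sp$freqs[1], 1)
  expect_identical(sp$freqs[which.max(sp$amplitude[1, ])], 10)
  expect_equal(sp$amplitude[1, sp$freqs == 10], 1, tolerance = 1e-6)
  # >= 90% of total power concentrates within +-1 Hz of the sinusoid
  pw <- sp$amplitude[1, ]^2
  expect_gte(sum(pw[sp$freqs >= 9 & sp$freqs <= 11]) / sum(pw), 0.9)
  # averaging identical segments is idempotent
  sp1 <- compute_spectrum(eeg, segs[1, ])
  sp2 <- compute_spectrum(eeg, segs[c(1, 1), ])
  expect_equal(sp1$amplitude, sp2$amplitude, tolerance = 1e-12)
  expect_error(compute_spectrum(eeg, segs[0, ]), "threshold")
})

test_that("white-noise spectra are flat across 4-40 Hz", {
  set.seed(21)
  fs <- 250
  n_seg <- 500
  eeg <- make_eeg(stats::rnorm(n_seg * fs), fs)
  segs <- data.frame(trial = 1L, segment = seq_len(n_seg),
                     start_sample = seq(1, n_seg * fs, by = fs),
                     end_sample = seq(fs + 1, n_seg * fs + 1, by = fs))
  sp <- compute_spectrum(eeg, segs)
  band <- sp$amplitude[1, sp$freqs >= 4 & sp$freqs <= 40]
  expect_lt(stats::sd(band) / mean(band), 0.2)
})

test_that("spectral parameterization recovers aperiodic and peak structure", {
  sp <- make_synth_spectrum()
  fit <- fit_spectral_model(sp, "Cz")
  expect_equal(fit$aperiodic_exponent, 1.5, tolerance = 0.2)
  expect_identical(nrow(fit$peaks), 1L)
  expect_equal(fit$peaks$center_hz[1], 10, tolerance = 0.5)

  flat <- make_synth_spectrum(peaks = list())
  fit0 <- fit_spectral_model(flat, "Cz")
  expect_identical(nrow(fit0$peaks), 0L)
  expect_equal(fit0$aperiodic_exponent, 1.5, tolerance = 0.05)

  two <- make_synth_spectrum(peaks = list(
    c(center = 10, height = 0.6, bw = 2),
    c(center = 6, height = 0.3, bw = 1.5)))
  fit2 <- fit_spectral_model(two, "Cz")
  expect_identical(nrow(fit2$peaks), 2L)
  # ordered by height above the aperiodic component
  expect_equal(fit2$peaks$center_hz, c(10, 6), tolerance = 0.5)
  expect_true(all(diff(fit2$peaks$height) <= 0))

  bad <- make_synth_spectrum()
  bad$amplitude[1, 20] <- NaN
  expect_error(fit_spectral_model(bad, "Cz"), "finite")
  expect_error(fit_spectral_model(sp, "Fz"), "unknown channel")
})

test_that("band peaks select the tallest in-band Gaussian with closed lower edge", {
  sp <- make_synth_spectrum(peaks = list(
    c(center = 10, height = 0.6, bw = 2),
    c(center = 12.5, height = 0.3, bw = 1)))
  fit <- fit_spectral_model(sp, "Cz")
  pk <- extract_band_peak(fit, sp, "alpha")
  expect_true(pk$found)
  expect_equal(pk$center_hz, 10, tolerance = 0.5)
  expect_equal(pk$power_value,
               sp$amplitude[1, which.min(abs(sp$freqs - pk$center_hz))]^2)

  # band boundary: a peak at exactly 7 Hz belongs to alpha, not theta
  # (closed lower edge); selection rule checked on a constructed fit
  fit7 <- structure(
    list(channel = "Cz", aperiodic_offset = 0.5, aperiodic_exponent = 1.5,
         peaks = data.frame(center_hz = 7, height = 0.6,
                            bandwidth_hz = 1.5),
         fit_range_hz = c(3, 40), goodness = 0),
    class = "spectral_fit")
  sp7 <- make_synth_spectrum(peaks = list(c(center = 7, height = 0.6,
                                            bw = 1.5)))
  expect_true(extract_band_peak(fit7, sp7, "alpha")$found)
  expect_false(extract_band_peak(fit7, sp7, "theta")$found)

  # no beta peak: fallback to max in-band raw power, flagged
  pkb <- extract_band_peak(fit, sp, "beta")
  expect_false(pkb$found)
  bins <- sp$freqs >= 20 & sp$freqs <= 30
  expect_equal(pkb$power_value, max(sp$amplitude[1, bins]^2))
})

test_that("peak recovery stays accurate across random alpha spectra", {
  set.seed(31)
  errs <- t(vapply(1:10, function(i) {
    cc <- stats::runif(1, 8, 12)
    sp <- make_synth_spectrum(peaks = list(c(center = cc, height = 0.5,
                                             bw = 2)),
                              noise_sd = 0.05)
    fit <- fit_spectral_model(sp, "Cz")
    pk <- extract_band_peak(fit, sp, "alpha")
    c(center = abs(pk$center_hz - cc),
      expo = abs(fit$aperiodic_exponent - 1.5))
  }, c(center = 0, expo = 0)))
  expect_lt(stats::median(errs[, "center"]), 0.3)
  expect_lt(stats::median(errs[, "expo"]), 0.2)
})
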