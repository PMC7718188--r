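test_that("eligibility requires 3 s pre-onset and 5 s ongoing vection", {
  tab <- make_trials(rep("coherent", 4), present = TRUE)
  tab$vection_onset_s <- c(2.5, 4.0, 4.0, 5.0)
  tab$vection_offset_s <- c(12.5, 10.0, 8.9, 19.0)
  tab$vection_present <- c(TRUE, TRUE, TRUE, FALSE)
  el <- select_eligible_trials(tab)
  expect_identical(el$trial, 2L)
  log <- attr(el, "log")
  expect_identical(log$reason[log$trial == 1], "onset_too_early")
  expect_identical(log$reason[log$trial == 3], "vection_too_short")
  expect_identical(log$reason[log$trial == 4], "no_vection")
})

test_that("onset epochs span exactly 8 s and preserve order", {
  fx <- fixture_session()
  el <- select_eligible_trials(fx$trials)
  ep <- extract_onset_epochs(fx$eeg, el)
  expect_gt(length(ep), 0)
  fs <- fx$eeg$sampling_rate
  for (e in ep) expect_identical(ncol(e$data), as.integer(8 * fs))
  expect_identical(vapply(ep, `[[`, 0L, "trial"), el$trial)
  expect_equal(ep[[1]]$times[1], -3)
  # an onset too close to the session start is dropped and logged
  fake <- el[1, ]
  fake$motion_onset_s <- 0.5
  fake$vection_onset_s <- 1.0
  ep2 <- extract_onset_epochs(fx$eeg, fake)
  expect_length(ep2, 0L)
  expect_identical(attr(ep2, "log")$reason, "outside_recording")
})

test_that("Morlet maps localize a pure sinusoid at its frequency", {
  fs <- 250
  times <- seq(-3, by = 1 / fs, length.out = 8 * fs)
  epoch <- structure(
    list(data = matrix(sin(2 * pi * 10 * times), 1),
         times = times, sampling_rate = fs, channel_labels = "Cz",
         trial = 1L),
    class = "eeg_epoch")
  tf <- morlet_tf(epoch, freqs = 3:40, cycles = 7)
  margin <- max(tf$margins_s)
  inside <- which(times > times[1] + margin &
                    times < times[length(times)] - margin)
  winners <- apply(tf$power[, inside, 1], 2, which.max)
  expect_true(all(tf$freqs[winners] == 10))
  # zero signal -> zero power
  epoch0 <- epoch
  epoch0$data[] <- 0
  tf0 <- morlet_tf(epoch0)
  expect_true(all(tf0$power == 0))
  expect_error(morlet_tf(epoch, freqs = c(10, 130)), "Nyquist")
})

test_that("a doubling of alpha amplitude quadruples Morlet power", {
  fs <- 250
  times <- seq(-3, by = 1 / fs, length.out = 8 * fs)
  amp <- ifelse(times < 0, 1, 2)
  epoch <- structure(
    list(data = matrix(amp * sin(2 * pi * 10 * times), 1),
         times = times, sampling_rate = fs, channel_labels = "Cz",
         trial = 1L),
    class = "eeg_epoch")
  tf <- morlet_tf(epoch)
  p10 <- tf$power[tf$freqs == 10, , 1]
  before <- mean(p10[times >= -2 & times < -1])
  after <- mean(p10[times >= 1 & times < 2])
  expect_equal(after / before, 4, tolerance = 0.15)
})

test_that("decibel normalization is exact, zero-mean on its interval, and single-shot", {
  # hand-built map: power 2x baseline -> +10 log10(2) dB
  times <- seq(-3, by = 0.01, length.out = 800)
  pw <- array(1, dim = c(2, 800, 1))
  pw[, times >= 0, ] <- 2
  tfmap <- structure(
    list(freqs = c(10, 11), times = times, power = pw, normalized = FALSE,
         wavelet_cycles = 7, channel_labels = "Cz", margins_s = c(0.35, 0.32)),
    class = "tf_map")
  norm <- db_normalize(tfmap)
  expect_equal(norm$power[1, times >= 0.5 & times < 1, 1],
               rep(10 * log10(2), 50), tolerance = 1e-12)
  sel <- times >= -2.5 & times < -1.5
  expect_equal(mean(norm$power[1, sel, 1]), 0, tolerance = 1e-12)
  expect_error(db_normalize(norm), "already")

  zero <- tfmap
  zero$power[] <- 0
  expect_error(db_normalize(zero), "zero")

  # stationary white noise stays within +-0.5 dB after trial averaging
  set.seed(61)
  fs <- 100
  t2 <- seq(-3, by = 1 / fs, length.out = 8 * fs)
  maps <- lapply(1:30, function(i) {
    ep <- structure(list(data = matrix(stats::rnorm(length(t2)), 1),
                         times = t2, sampling_rate = fs,
                         channel_labels = "Cz", trial = i),
                    class = "eeg_epoch")
    morlet_tf(ep, freqs = seq(5, 35, by = 5))
  })
  norm2 <- db_normalize(tf_average(maps))
  interior <- t2 >= -2.5 & t2 < 4
  expect_lt(abs(mean(norm2$power[, interior, 1])), 0.5)
})

test_that("ROI time-courses average channels and honour the analysis windows", {
  times <- seq(-3, by = 0.01, length.out = 800)
  pw1 <- array(stats::runif(3 * 800), dim = c(3, 800, 1))
  pw <- array(c(pw1, pw1), dim = c(3, 800, 2))  # two identical channels
  tfmap <- structure(
    list(freqs = c(8, 10, 12), times = times, power = pw,
         normalized = FALSE, wavelet_cycles = 7,
         channel_labels = c("CP1", "P3"), margins_s = rep(0.4, 3)),
    class = "tf_map")
  norm <- db_normalize(tfmap)
  both <- roi_alpha_timecourse(norm, c("CP1", "P3"))
  one <- roi_alpha_timecourse(norm, "CP1")
  expect_equal(both$values, one$values, tolerance = 1e-12)
  # vection window covers exactly 4.5 s of samples
  expect_identical(length(both$vection_times), as.integer(4.5 * 100))
  expect_equal(both$baseline_mean,
               mean(both$values[times >= -1.5 & times < -0.5]),
               tolerance = 1e-12)
  expect_error(roi_alpha_timecourse(norm, character(0)), "empty")
  expect_error(roi_alpha_timecourse(norm, "Pz"), "missing")
  expect_error(roi_alpha_timecourse(tfmap, "CP1"), "normalize")
  # both study ROI label sets resolve against the standard montage
  mon <- fixture_montage()
  expect_true(all(roi_electrodes("left") %in% mon$labels))
  expect_true(all(roi_electrodes("midline") %in% mon$labels))
})

test_that("the subject-level trace shows the injected dip and rise", {
  fx <- fixture_session()
  tc <- subject_roi_timecourse(fx$eeg, fx$trials, fx$profile$roi_labels,
                               decimate_by = 5)
  expect_s3_class(tc, "roi_timecourse")
  expect_equal(tc$grid_hz, 50)
  dip <- tc$vection_times >= -0.45 & tc$vection_times < -0.05
  rise <- tc$vection_times >= 2 & tc$vection_times < 3.5
  expect_lt(mean(tc$vection_values[dip]), -0.4)
  expect_gt(mean(tc$vection_values[rise]), 0.4)
  expect_lt(abs(tc$baseline_mean), 0.4)
})
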