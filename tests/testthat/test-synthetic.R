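test_that("coherent dot fields rotate rigidly at the design speed", {
  dk <- generate_dot_stimulus("coherent", "CW", 5, seed = 1, n_dots = 50)
  expect_equal(mean_angular_velocity(dk), -30, tolerance = 1e-9)
  dk2 <- generate_dot_stimulus("coherent", "CCW", 5, seed = 1, n_dots = 50)
  expect_equal(mean_angular_velocity(dk2), 30, tolerance = 1e-9)
  # per-dot velocities are all exactly the global speed
  th <- dk$angular_position
  step <- (th[, -1] - th[, -ncol(th)] + 180) %% 360 - 180
  per_dot <- rowSums(step) / ((ncol(th) - 1) / dk$frame_rate)
  expect_equal(per_dot, rep(-30, 50), tolerance = 1e-9)
  expect_true(all(th >= 0 & th < 360))
})

test_that("incoherent dot fields keep the global mean velocity within 0.5 deg/s", {
  dk <- generate_dot_stimulus("incoherent", "CCW", 20, seed = 1)
  expect_lt(abs(mean_angular_velocity(dk) - 30), 0.5)
  dk2 <- generate_dot_stimulus("incoherent", "CW", 20, seed = 2)
  expect_lt(abs(mean_angular_velocity(dk2) + 30), 0.5)
  # individual dots wobble: per-dot instantaneous velocity is not constant
  th <- dk$angular_position
  step <- (th[, -1] - th[, -ncol(th)] + 180) %% 360 - 180
  expect_gt(mean(apply(step, 1, stats::sd)), 0)
})

test_that("degenerate stimulus arguments are rejected and seeds reproduce", {
  expect_error(generate_dot_stimulus("coherent", "CW", 0), "positive")
  expect_error(generate_dot_stimulus("coherent", "CW", -1), "positive")
  a <- generate_dot_stimulus("incoherent", "CW", 2, seed = 9, n_dots = 20)
  b <- generate_dot_stimulus("incoherent", "CW", 2, seed = 9, n_dots = 20)
  expect_identical(a, b)
})

test_that("generated sessions follow the trial-count design", {
  trials <- generate_behaviour(seed = 42)
  main <- main_trials(trials)
  expect_identical(nrow(main), 100L)
  expect_identical(sum(main$condition == "coherent"), 50L)
  expect_identical(sum(main$condition == "incoherent"), 50L)
  tab <- table(main$condition, main$direction)
  expect_true(all(tab == 25L))
  prac <- trials[trials$is_practice, ]
  expect_identical(nrow(prac), 12L)
  expect_true(all(table(prac$condition) == 6L))
  expect_true(all(table(prac$condition, prac$direction) == 3L))
  # determinism
  expect_identical(generate_behaviour(seed = 42), trials)
})

test_that("behavioural draws respect their distributions and constraints", {
  prof <- subject_profile("right",
                          presence_prob = c(coherent = 0.95, incoherent = 0))
  trials <- generate_behaviour(profile = prof, seed = 5)
  main <- main_trials(trials)
  inc <- main[main$condition == "incoherent", ]
  expect_true(all(!inc$vection_present))
  expect_true(all(inc$strength == 0L))
  coh <- main[main$condition == "coherent" & main$vection_present, ]
  expect_true(all(coh$vection_onset_s > 0 & coh$vection_onset_s < 20))
  expect_true(all(coh$vection_offset_s > coh$vection_onset_s))
  expect_true(all(coh$vection_offset_s <= 20))
  expect_true(all(main$strength >= 0L & main$strength <= 10L))
  # one onset and one offset button per vection-present main trial
  b <- button_events(trials)
  expect_identical(nrow(b), 2L * nrow(coh))
  expect_false(is.unsorted(b$time_s))
})

test_that("EEG sessions conserve samples and carry one marker set per trial", {
  fx <- fixture_session()
  eeg <- fx$eeg
  main <- main_trials(fx$trials)
  expected_samples <- round(
    (max(main$motion_offset_s) + fx$design$post_duration) *
      fx$design$sampling_rate)
  expect_identical(ncol(eeg$data), as.integer(expected_samples))
  expect_identical(nrow(eeg$data), 64L)
  expect_identical(sum(eeg$events$code == "motion_on"), nrow(main))
  expect_identical(sum(eeg$events$code == "motion_off"), nrow(main))
  expect_identical(sum(eeg$events$code == "vection_on"),
                   sum(main$vection_present))
  expect_false(is.unsorted(eeg$events$sample))
  expect_true(all(eeg$events$sample >= 1 &
                    eeg$events$sample <= ncol(eeg$data)))
  expect_true(all(is.finite(eeg$data)))
})

test_that("the rotation-period spectrum peaks at the profile's alpha frequency", {
  fx <- fixture_session()
  segs <- segment_rotation_periods(fx$eeg, fx$trials, "incoherent")
  segs <- reject_segments(fx$eeg, segs, button_events(fx$trials))
  sp <- compute_spectrum(fx$eeg, segs)
  grand <- colMeans(sp$amplitude)
  band <- sp$freqs >= 4 & sp$freqs <= 30
  peak_f <- sp$freqs[band][which.max(grand[band])]
  expect_equal(peak_f, fx$profile$alpha_peak_hz, tolerance = 0.5)
})

test_that("injected coherent alpha drop is recovered as a ~0.7 ROI power ratio", {
  # 10 subjects at reduced scale; the spectral module estimates the
  # coherent/incoherent alpha-peak power ratio at the ROI electrodes
  mon <- fixture_montage()
  design <- experiment_design(n_coherent = 6, n_incoherent = 6,
                              sampling_rate = 250)
  profile <- subject_profile("left", coherent_alpha_drop = 0.3,
                             onset_locked_params = c(dip_db = 0,
                                                     dip_lead_s = 0.5,
                                                     rise_db = 0,
                                                     rise_lag_s = 1.5))
  ratios <- vapply(1:10, function(i) {
    trials <- generate_behaviour(design, profile, seed = 300 + i)
    eeg <- generate_eeg_session(design, profile, mon, trials,
                                seed = 400 + i)
    ratio_for <- function(cond) {
      segs <- segment_rotation_periods(eeg, trials, cond)
      segs <- reject_segments(eeg, segs, button_events(trials))
      sp <- compute_spectrum(eeg, segs)
      pk <- band_peak_powers(sp, "alpha")
      pk$power_value[match(profile$roi_labels, pk$channel)]
    }
    mean(ratio_for("coherent") / ratio_for("incoherent"))
  }, 0)
  expect_lt(abs(mean(ratios) - 0.7), 0.1)
})

test_that("null-mode sessions are exchangeable across conditions", {
  # with no injected effect, per-electrode permutation p values over a
  # small cohort are compatible with the uniform distribution
  mon <- fixture_montage()
  design <- experiment_design(n_coherent = 4, n_incoherent = 4,
                              sampling_rate = 250)
  profile <- subject_profile("left", coherent_alpha_drop = 0,
                             onset_locked_params = c(dip_db = 0,
                                                     dip_lead_s = 0.5,
                                                     rise_db = 0,
                                                     rise_lag_s = 1.5))
  alpha_power <- function(i) {
    trials <- generate_behaviour(design, profile, seed = 500 + i)
    eeg <- generate_eeg_session(design, profile, mon, trials,
                                seed = 600 + i)
    per_cond <- function(cond) {
      segs <- segment_rotation_periods(eeg, trials, cond)
      segs <- reject_segments(eeg, segs, button_events(trials))
      sp <- compute_spectrum(eeg, segs)
      bin <- which.min(abs(sp$freqs - profile$alpha_peak_hz))
      sp$amplitude[, bin]^2
    }
    rbind(coherent = per_cond("coherent"),
          incoherent = per_cond("incoherent"))
  }
  mats <- lapply(1:10, alpha_power)
  coh <- do.call(rbind, lapply(mats, function(m) m["coherent", ]))
  inc <- do.call(rbind, lapply(mats, function(m) m["incoherent", ]))
  pvals <- vapply(seq_len(ncol(coh)), function(e) {
    paired_shuffle_test(coh[, e], inc[, e], n_iter = 500,
                        seed = 700 + e)$p_value
  }, 0)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort generation is reproducible and group-structured", {
  design <- experiment_design(n_coherent = 4, n_incoherent = 4,
                              sampling_rate = 250)
  cohort <- generate_cohort(2, design, seed = 11, eeg = FALSE)
  expect_length(cohort, 4L)
  expect_identical(vapply(cohort, `[[`, "", "group"),
                   c("left", "left", "right", "right"))
  expect_identical(cohort[[1]]$profile$roi_labels, roi_electrodes("left"))
  expect_identical(cohort[[3]]$profile$roi_labels,
                   roi_electrodes("midline"))
  cohort2 <- generate_cohort(2, design, seed = 11, eeg = FALSE)
  expect_identical(cohort, cohort2)
  # per-subject seeds differ: different subjects get different trials
  expect_false(identical(cohort[[1]]$trials$motion_onset_s,
                         cohort[[2]]$trials$motion_onset_s))
})

test_that("button artifact repair removes the pulse but keeps the background", {
  fx <- fixture_session()
  b <- button_events(fx$trials)
  repaired <- repair_button_artifacts(fx$eeg, b)
  i0 <- round(b$time_s[1] * fx$eeg$sampling_rate) + 1
  idx <- i0:(i0 + round(0.05 * fx$eeg$sampling_rate))
  expect_gt(max(abs(fx$eeg$data[1, idx])), 100)
  expect_lt(max(abs(repaired$data[1, idx])), 100)
  untouched <- seq(100, i0 - 50)
  expect_identical(repaired$data[, untouched], fx$eeg$data[, untouched])
})
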