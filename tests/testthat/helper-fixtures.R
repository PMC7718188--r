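# Shared fixtures, built once per test run. Simulation sizes are reduced
# relative to the full study design (fewer trials, 250 Hz) so the suite
# stays fast; the generators themselves default to the study design.

.fixture_cache <- new.env(parent = emptyenv())

fixture_montage <- function() {
  if (is.null(.fixture_cache$montage)) {
    .fixture_cache$montage <- build_standard_montage()
  }
  .fixture_cache$montage
}

# one left-handed subject: 10 coherent + 10 incoherent trials at 250 Hz
fixture_session <- function() {
  if (is.null(.fixture_cache$session)) {
    design <- experiment_design(n_coherent = 10, n_incoherent = 10,
                                sampling_rate = 250)
    profile <- subject_profile("left")
    trials <- generate_behaviour(design, profile, seed = 7)
    eeg <- generate_eeg_session(design, profile, fixture_montage(), trials,
                                seed = 8)
    .fixture_cache$session <- list(design = design, profile = profile,
                                   trials = trials, eeg = eeg)
  }
  .fixture_cache$session
}

# minimal eeg_session wrapper around a raw data matrix
make_eeg <- function(data, fs, labels = NULL, events = NULL) {
  if (is.null(dim(data))) data <- matrix(data, nrow = 1L)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  if (is.null(events)) {
    events <- data.frame(sample = integer(0), code = character(0),
                         trial = integer(0))
  }
  structure(list(channel_labels = labels, data = data, sampling_rate = fs,
                 events = events),
            class = "eeg_session")
}

# noise-free synthetic amplitude spectrum: 1/f background plus Gaussians
# (in log10 power), on a 1 Hz grid to `fmax`
make_synth_spectrum <- function(peaks = list(c(center = 10, height = 0.6,
                                               bw = 2)),
                                exponent = 1.5, offset = 0.5, fmax = 125,
                                noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  freqs <- 0:fmax
  lp <- ifelse(freqs > 0, offset - exponent * log10(pmax(freqs, 1e-9)),
               offset)
  for (pk in peaks) {
    lp <- lp + pk[["height"]] *
      exp(-(freqs - pk[["center"]])^2 / (2 * pk[["bw"]]^2))
  }
  if (noise_sd > 0) lp <- lp + stats::rnorm(length(lp), 0, noise_sd)
  amp <- sqrt(10^lp)
  amp[1] <- amp[2]
  structure(list(freqs = freqs, amplitude = matrix(amp, 1L),
                 n_segments = 1L, channel_labels = "Cz"),
            class = "eeg_spectrum")
}

# minimal trial table for behavioural unit tests
make_trials <- function(condition, present, onset = NA, offset = NA,
                        strength = 0, direction = "CW") {
  n <- max(length(condition), length(present), length(onset),
           length(offset), length(strength), length(direction))
  tab <- data.frame(
    trial = seq_len(n),
    is_practice = FALSE,
    main_index = seq_len(n),
    block = 1L,
    condition = rep_len(condition, n),
    direction = rep_len(direction, n),
    motion_onset_s = 10 * seq_len(n),
    motion_offset_s = 10 * seq_len(n) + 20,
    vection_present = rep_len(present, n),
    vection_onset_s = rep_len(as.numeric(onset), n),
    vection_offset_s = rep_len(as.numeric(offset), n),
    strength = rep_len(as.integer(strength), n)
  )
  class(tab) <- c("trial_table", "data.frame")
  tab
}
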