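#' Experimental design parameters
#'
#' Describes one session of the optokinetic roll-vection experiment: 100
#' main trials (50 coherent, 50 incoherent, 25 per rotation direction
#' within each condition) presented in randomized blocks of 10, preceded
#' by 12 practice trials. Each trial is a jittered stationary period
#' (3-5 s), 20 s of dot rotation at 30 deg/s, and 10 s of stationary dots.
#' EEG is sampled at 1000 Hz.
#'
#' Non-default values (fewer trials, lower sampling rate, shorter rotation)
#' are accepted so that simulation studies can run at reduced scale; the
#' defaults are the study design.
#'
#' @param n_coherent,n_incoherent Main-trial counts per condition.
#' @param pre_jitter_range Length-2 numeric, seconds of stationary dots
#'   before rotation (uniform jitter).
#' @param rotation_duration,post_duration Seconds of rotation / post-trial
#'   stationary dots.
#' @param block_size Trials per presentation block.
#' @param practice_trials Number of practice trials (balanced over
#'   condition and direction; no EEG is recorded during practice).
#' @param sampling_rate EEG sampling rate, Hz.
#' @param rotation_speed Global angular speed of the dot field, deg/s.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(n_coherent = 50L,
                              n_incoherent = 50L,
                              pre_jitter_range = c(3, 5),
                              rotation_duration = 20,
                              post_duration = 10,
                              block_size = 10L,
                              practice_trials = 12L,
                              sampling_rate = 1000,
                              rotation_speed = 30) {
  stopifnot(n_coherent >= 2, n_incoherent >= 2,
            n_coherent %% 2 == 0, n_incoherent %% 2 == 0,
            length(pre_jitter_range) == 2L,
            pre_jitter_range[1] > 0,
            pre_jitter_range[2] >= pre_jitter_range[1],
            rotation_duration > 0, post_duration >= 0,
            block_size >= 1, practice_trials >= 0,
            practice_trials %% 4 == 0,
            sampling_rate > 0, rotation_speed > 0)
  structure(
    list(n_coherent = as.integer(n_coherent),
         n_incoherent = as.integer(n_incoherent),
         n_per_direction = as.integer(n_coherent) %/% 2L,
         pre_jitter_range = as.numeric(pre_jitter_range),
         rotation_duration = rotation_duration,
         post_duration = post_duration,
         block_size = as.integer(block_size),
         practice_trials = as.integer(practice_trials),
         sampling_rate = sampling_rate,
         rotation_speed = rotation_speed),
    class = "experiment_design"
  )
}

#' Synthetic subject profile
#'
#' Parameterizes everything subject-specific in the generator: spectral
#' background, the alpha oscillation and its condition-dependent power
#' drop at the region-of-interest electrodes, the vection-onset-locked
#' alpha envelope, and the behavioural response distributions.
#'
#' The onset-locked envelope has four parameters: a dip of `dip_db`
#' decibels starting `dip_lead_s` seconds before each vection onset, and a
#' sustained rise of `rise_db` decibels starting `rise_lag_s` seconds
#' after onset and lasting until vection offset.
#'
#' Behavioural defaults target the group medians of the study loosely
#' (coherent: presence ~95%, onset ~5.8 s, duration ~12.8 s, strength ~5;
#' incoherent: presence ~6%, onset ~11.7 s, duration ~4.5 s) with
#' log-normal onset/duration distributions and a linear habituation drift
#' of the strength rating across trials.
#'
#' @param handedness `"left"` or `"right"`.
#' @param ehi_score Edinburgh Handedness Inventory score in -100..100
#'   (label only; negative for left handers by convention).
#' @param alpha_peak_hz Individual alpha peak frequency, Hz (7-14).
#' @param aperiodic_exponent,aperiodic_offset 1/f background: power
#'   ~ offset / f^exponent (offset in muV^2 log10 units).
#' @param roi_labels Electrodes carrying the condition-dependent alpha
#'   modulation; defaults to the left set for left handers and the midline
#'   set for right handers.
#' @param coherent_alpha_drop Fractional alpha-power decrease at
#'   `roi_labels` during coherent rotation, in \[0, 1).
#' @param onset_locked_params Named numeric: `dip_db`, `dip_lead_s`,
#'   `rise_db`, `rise_lag_s`.
#' @param presence_prob Named probabilities of reporting vection, per
#'   condition.
#' @param onset_meanlog,onset_sdlog Log-normal onset-latency parameters
#'   per condition (named vectors).
#' @param duration_meanlog,duration_sdlog Log-normal vection-duration
#'   parameters per condition.
#' @param strength_mean,strength_sd Normal parameters of the 0-10 strength
#'   rating before rounding (vection-present trials).
#' @param habituation_slope Strength-units decrease per main trial.
#' @param alpha_amp_uv,noise_sd_uv Alpha sinusoid amplitude and 1/f
#'   background standard deviation, microvolts.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(handedness = c("right", "left"),
                            ehi_score = NULL,
                            alpha_peak_hz = 10,
                            aperiodic_exponent = 1.5,
                            aperiodic_offset = 0,
                            roi_labels = NULL,
                            coherent_alpha_drop = 0.3,
                            onset_locked_params = c(dip_db = -1.5,
                                                    dip_lead_s = 0.5,
                                                    rise_db = 1.0,
                                                    rise_lag_s = 1.5),
                            presence_prob = c(coherent = 0.95,
                                              incoherent = 0.06),
                            onset_meanlog = c(coherent = log(5.8),
                                              incoherent = log(11.7)),
                            onset_sdlog = c(coherent = 0.45,
                                            incoherent = 0.3),
                            duration_meanlog = c(coherent = log(12.8),
                                                 incoherent = log(4.5)),
                            duration_sdlog = c(coherent = 0.35,
                                               incoherent = 0.4),
                            strength_mean = c(coherent = 5.3,
                                              incoherent = 2.0),
                            strength_sd = 1.8,
                            habituation_slope = 0.003,
                            alpha_amp_uv = 5,
                            noise_sd_uv = 10) {
  handedness <- match.arg(handedness)
  if (is.null(ehi_score)) {
    ehi_score <- if (handedness == "right") 80 else -80
  }
  if (is.null(roi_labels)) {
    roi_labels <- roi_electrodes(if (handedness == "left") "left" else "midline")
  }
  stopifnot(alpha_peak_hz >= 7, alpha_peak_hz <= 14,
            abs(ehi_score) <= 100,
            coherent_alpha_drop >= 0, coherent_alpha_drop < 1,
            all(presence_prob >= 0), all(presence_prob <= 1),
            all(c("dip_db", "dip_lead_s", "rise_db", "rise_lag_s") %in%
                  names(onset_locked_params)),
            strength_sd > 0, alpha_amp_uv >= 0, noise_sd_uv > 0)
  structure(
    list(handedness = handedness,
         ehi_score = ehi_score,
         alpha_peak_hz = alpha_peak_hz,
         aperiodic_exponent = aperiodic_exponent,
         aperiodic_offset = aperiodic_offset,
         roi_labels = roi_labels,
         coherent_alpha_drop = coherent_alpha_drop,
         onset_locked_params = onset_locked_params,
         presence_prob = presence_prob,
         onset_meanlog = onset_meanlog,
         onset_sdlog = onset_sdlog,
         duration_meanlog = duration_meanlog,
         duration_sdlog = duration_sdlog,
         strength_mean = strength_mean,
         strength_sd = strength_sd,
         habituation_slope = habituation_slope,
         alpha_amp_uv = alpha_amp_uv,
         noise_sd_uv = noise_sd_uv),
    class = "subject_profile"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(paste0("<experiment_design> %d+%d main trials (%d/direction),",
                     " %d practice\n"),
              x$n_coherent, x$n_incoherent, x$n_per_direction,
              x$practice_trials))
  cat(sprintf("  jitter %.1f-%.1f s | rotation %.0f s @ %.0f deg/s | post %.0f s | fs %.0f Hz\n",
              x$pre_jitter_range[1], x$pre_jitter_range[2],
              x$rotation_duration, x$rotation_speed, x$post_duration,
              x$sampling_rate))
  invisible(x)
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> %s-handed (EHI %+d), alpha %.1f Hz, drop %.2f at [%s]\n",
              x$handedness, as.integer(x$ehi_score), x$alpha_peak_hz,
              x$coherent_alpha_drop, paste(x$roi_labels, collapse = " ")))
  invisible(x)
}
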