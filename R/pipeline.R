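#' Pipeline configuration
#'
#' Bundles every parameter of the simulate -> behaviour -> spectral ->
#' stats -> time-frequency pipeline with the study defaults: 25 subjects
#' per handedness group, 1000-iteration permutation tests thresholded at
#' p < 0.05, alpha-band peaks fitted over 3-40 Hz, 20-sequential-point
#' temporal clusters, 7-cycle Morlet wavelets on 3-40 Hz, and the 100 muV
#' segment-rejection rule.
#'
#' @param n_per_group Subjects per handedness group.
#' @param design An [experiment_design()].
#' @param profiles Named list of [subject_profile()]s (`left`, `right`).
#' @param montage_factor Adjacency threshold factor for
#'   [build_standard_montage()].
#' @param alpha_thresh A priori electrode/timepoint threshold.
#' @param n_iter Permutation iterations.
#' @param band Band analysed spatially (`"alpha"`).
#' @param fit_range_hz Spectral-fit range.
#' @param reject_threshold_uv Segment rejection amplitude.
#' @param min_run Minimum temporal-cluster length (timepoints on the
#'   analysis grid).
#' @param tf_freqs,tf_cycles Morlet parameters.
#' @param decimate_by Time-grid subsampling for the ROI trace.
#' @param seed Master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_per_group = 25L,
                            design = experiment_design(),
                            profiles = list(left = subject_profile("left"),
                                            right = subject_profile("right")),
                            montage_factor = 1.3,
                            alpha_thresh = 0.05,
                            n_iter = 1000L,
                            band = "alpha",
                            fit_range_hz = c(3, 40),
                            reject_threshold_uv = 100,
                            min_run = 20L,
                            tf_freqs = 3:40,
                            tf_cycles = 7,
                            decimate_by = 1L,
                            seed = 1L) {
  stopifnot(n_per_group >= 1, inherits(design, "experiment_design"),
            all(c("left", "right") %in% names(profiles)),
            n_iter >= 1, min_run >= 1)
  structure(
    list(n_per_group = as.integer(n_per_group), design = design,
         profiles = profiles, montage_factor = montage_factor,
         alpha_thresh = alpha_thresh, n_iter = as.integer(n_iter),
         band = band, fit_range_hz = fit_range_hz,
         reject_threshold_uv = reject_threshold_uv,
         min_run = as.integer(min_run), tf_freqs = as.numeric(tf_freqs),
         tf_cycles = tf_cycles, decimate_by = as.integer(decimate_by),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Serialize / restore a pipeline configuration (YAML)
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `path` (write) or the restored `pipeline_config` (read).
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- unclass(config)
  plain$design <- unclass(config$design)
  plain$design$n_per_direction <- NULL
  plain$profiles <- lapply(config$profiles, function(p) {
    q <- unclass(p)
    q$onset_locked_params <- as.list(q$onset_locked_params)
    q$presence_prob <- as.list(q$presence_prob)
    q$onset_meanlog <- as.list(q$onset_meanlog)
    q$onset_sdlog <- as.list(q$onset_sdlog)
    q$duration_meanlog <- as.list(q$duration_meanlog)
    q$duration_sdlog <- as.list(q$duration_sdlog)
    q$strength_mean <- as.list(q$strength_mean)
    q
  })
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  plain <- yaml::read_yaml(path)
  design <- do.call(experiment_design, plain$design)
  profiles <- lapply(plain$profiles, function(q) {
    for (f in c("onset_locked_params", "presence_prob", "onset_meanlog",
                "onset_sdlog", "duration_meanlog", "duration_sdlog",
                "strength_mean")) {
      q[[f]] <- unlist(q[[f]])
    }
    do.call(subject_profile, q)
  })
  args <- plain[setdiff(names(plain), c("design", "profiles"))]
  do.call(pipeline_config,
          c(list(design = design, profiles = profiles), args))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Simulates the cohort, then runs the behavioural statistics, the
#' per-electrode spectral peak extraction with the spatial cluster test
#' (per handedness group), and the onset-locked time-frequency analysis
#' with the temporal cluster test. The temporal-test ROI of each group is
#' taken from that group's most significant negative spatial cluster
#' when one reaches the alpha threshold, otherwise from the group
#' profile's default ROI.
#'
#' @param config A `pipeline_config`.
#' @return A `report_bundle`: `behavioural` (per-subject summary table,
#'   group tests, direction screening, habituation), `spectral` (per
#'   group: subjects x electrodes peak-power matrices), `spatial`
#'   (per-group `cluster_set`), `temporal` (per-group ROI traces and
#'   `temporal_cluster_set`), `provenance` (seed, iteration counts,
#'   package version).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  montage <- with_stage("montage",
    build_standard_montage(neighbour_factor = config$montage_factor))
  cohort <- with_stage("simulate",
    generate_cohort(config$n_per_group, config$design, montage,
                    config$profiles, seed = config$seed))
  groups <- split(cohort, vapply(cohort, `[[`, "", "group"))

  behavioural <- with_stage("behaviour", {
    summaries <- do.call(rbind, lapply(cohort, function(s) {
      rbind(cbind(subject = s$id, group = s$group,
                  summarize_subject(s$trials, "coherent")),
            cbind(subject = s$id, group = s$group,
                  summarize_subject(s$trials, "incoherent")))
    }))
    measures <- c("presence_pct", "median_onset_s", "median_duration_s",
                  "median_strength")
    group_tests <- list()
    for (cond in c("coherent", "incoherent")) {
      for (m in measures) {
        va <- summaries[summaries$group == "left" &
                          summaries$condition == cond, m]
        vb <- summaries[summaries$group == "right" &
                          summaries$condition == cond, m]
        va <- va[is.finite(va)]
        vb <- vb[is.finite(vb)]
        group_tests[[paste(cond, m, sep = ".")]] <-
          if (length(va) >= 2 && length(vb) >= 2) {
            compare_groups(va, vb)
          } else NULL
      }
    }
    direction_tests <- list()
    for (grp in names(groups)) {
      for (cond in c("coherent", "incoherent")) {
        for (m in measures) {
          cw <- vapply(groups[[grp]], function(s)
            summarize_subject(s$trials, cond, "CW")[[m]], 0)
          ccw <- vapply(groups[[grp]], function(s)
            summarize_subject(s$trials, cond, "CCW")[[m]], 0)
          ok <- is.finite(cw) & is.finite(ccw)
          direction_tests[[paste(grp, cond, m, sep = ".")]] <-
            if (sum(ok) >= 2) {
              compare_directions(cw[ok], ccw[ok], family_size = 16)
            } else NULL
        }
      }
    }
    habituation <- lapply(
      stats::setNames(c("coherent", "incoherent"),
                      c("coherent", "incoherent")),
      function(cond) habituation_correlation(
        lapply(cohort, `[[`, "trials"), cond))
    list(summaries = summaries, group_tests = group_tests,
         direction_tests = direction_tests, habituation = habituation)
  })

  spectral <- with_stage("spectral", {
    lapply(groups, function(subjects) {
      mats <- lapply(c(coherent = "coherent", incoherent = "incoherent"),
                     function(cond) {
        rows <- lapply(subjects, function(s) {
          segs <- segment_rotation_periods(s$eeg, s$trials, cond)
          segs <- reject_segments(s$eeg, segs, button_events(s$trials),
                                  config$reject_threshold_uv)
          pk <- band_peak_powers(compute_spectrum(s$eeg, segs),
                                 config$band, config$fit_range_hz)
          stats::setNames(pk$power_value, pk$channel)
        })
        do.call(rbind, rows)
      })
      mats
    })
  })

  spatial <- with_stage("spatial_stats", {
    res <- list()
    for (grp in names(groups)) {
      res[[grp]] <- spatial_cluster_test(
        spectral[[grp]]$coherent, spectral[[grp]]$incoherent, montage,
        alpha_thresh = config$alpha_thresh, n_iter = config$n_iter,
        seed = config$seed + 101L)
    }
    res
  })

  temporal <- with_stage("temporal_stats", {
    res <- list()
    for (grp in names(groups)) {
      neg <- Filter(function(cl) cl$sign == "negative" &&
                      cl$p_value < config$alpha_thresh, spatial[[grp]])
      roi <- if (length(neg)) neg[[1L]]$members else
        config$profiles[[grp]]$roi_labels
      traces <- lapply(groups[[grp]], function(s) {
        subject_roi_timecourse(s$eeg, s$trials, roi,
                               freqs = config$tf_freqs,
                               cycles = config$tf_cycles,
                               decimate_by = config$decimate_by)
      })
      traces <- Filter(Negate(is.null), traces)
      if (length(traces) < 2L) {
        res[[grp]] <- list(roi = roi, traces = traces, clusters = NULL)
      } else {
        baseline <- vapply(traces, `[[`, 0, "baseline_mean")
        trace_mat <- do.call(rbind,
                             lapply(traces, `[[`, "vection_values"))
        clusters <- temporal_cluster_test(
          baseline, trace_mat, min_run = config$min_run,
          alpha_thresh = config$alpha_thresh, n_iter = config$n_iter,
          seed = config$seed + 202L)
        res[[grp]] <- list(roi = roi, traces = traces,
                           times = traces[[1L]]$vection_times,
                           clusters = clusters)
      }
    }
    res
  })

  structure(
    list(behavioural = behavioural, spectral = spectral,
         spatial = spatial, temporal = temporal,
         provenance = list(
           seed = config$seed, n_iter = config$n_iter,
           n_per_group = config$n_per_group,
           package_version = as.character(utils::packageVersion("vectionEEG")))),
    class = "report_bundle"
  )
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> seed %d, %d subjects/group\n",
              x$provenance$seed, x$provenance$n_per_group))
  for (grp in names(x$spatial)) {
    sig <- Filter(function(cl) cl$p_value < 0.05, x$spatial[[grp]])
    cat(sprintf("  %s handers: %d spatial cluster(s), %d significant\n",
                grp, length(x$spatial[[grp]]), length(sig)))
  }
  invisible(x)
}

#' Write / read a session as a plain-text bundle
#'
#' Serializes an EEG session and its trial table into a directory of
#' tab-separated text files (`data.tsv`: samples x channels; `events.tsv`;
#' `trials.tsv`; `buttons.tsv`) plus `meta.yaml`, and restores it
#' losslessly (event sample indices and trial fields exactly; amplitudes
#' to double-precision text round-trip).
#'
#' @param eeg An `eeg_session`.
#' @param trials The session's trial table.
#' @param dir Directory to create/read.
#' @return `dir` (write) or a list `(eeg, trials)` (read).
#' @export
write_session <- function(eeg, trials, dir) {
  stopifnot(inherits(eeg, "eeg_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dat <- as.data.frame(t(eeg$data))
  names(dat) <- eeg$channel_labels
  utils::write.table(format(dat, digits = 17, trim = TRUE, scientific = TRUE),
                     file.path(dir, "data.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(eeg$events, file.path(dir, "events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(trials), file.path(dir, "trials.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(button_events(trials), file.path(dir, "buttons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(sampling_rate = eeg$sampling_rate,
                        n_channels = nrow(eeg$data),
                        n_samples = ncol(eeg$data)),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  need <- c("data.tsv", "events.tsv", "trials.tsv", "buttons.tsv",
            "meta.yaml")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("session bundle is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  dat <- tryCatch(
    utils::read.table(file.path(dir, "data.tsv"), header = TRUE,
                      sep = "\t", check.names = FALSE),
    error = function(e) stop("malformed data.tsv: ", conditionMessage(e),
                             call. = FALSE))
  if (nrow(dat) != meta$n_samples || ncol(dat) != meta$n_channels) {
    stop("data.tsv dimensions disagree with meta.yaml (truncated file?)",
         call. = FALSE)
  }
  events <- utils::read.table(file.path(dir, "events.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  trials <- utils::read.table(file.path(dir, "trials.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  buttons <- utils::read.table(file.path(dir, "buttons.tsv"), header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
  bad <- which(!is.na(trials$strength) &
                 (trials$strength < 0 | trials$strength > 10))
  if (length(bad)) {
    stop("trials.tsv row ", bad[1L],
         ": strength outside the 0-10 scale", call. = FALSE)
  }
  if (is.unsorted(events$sample)) {
    stop("events.tsv is not sorted by sample", call. = FALSE)
  }
  attr(trials, "buttons") <- buttons
  class(trials) <- c("trial_table", "data.frame")
  eeg <- structure(
    list(channel_labels = names(dat),
         data = t(as.matrix(dat)),
         sampling_rate = meta$sampling_rate,
         events = events),
    class = "eeg_session"
  )
  list(eeg = eeg, trials = trials)
}
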