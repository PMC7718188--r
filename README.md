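# vectionEEG

Simulation and analysis of EEG alpha-band correlates of visually induced
self-motion perception (vection).

When a stationary observer watches a large-field rotating dot pattern,
they often perceive illusory self-rotation — roll vection. EEG studies of
this phenomenon contrast a *coherent* stimulus (all dots rotating rigidly
at 30°/s, strongly vection-inducing) with an *incoherent* control (each
dot's trajectory perturbed by a per-dot randomized sinusoid while the
global pattern keeps the same mean rotation), and look for alpha-band
(7–14 Hz) power changes: a decrease at centro-parietal electrodes during
coherent stimulation, and onset-locked dynamics — a brief alpha decrease
just before the reported vection onset followed by a sustained relative
increase during ongoing vection. Because such recordings are rarely
public, this package pairs the full analysis chain with a synthetic
session generator that reproduces the experimental design, so every
stage is testable end to end.

The package is aimed at EEG methodologists who want a tested, seedable
reference implementation of this analysis style, and at simulation
studies of its statistical behaviour (error control, power, recovery).

## What it implements

**Synthetic sessions.** Dot-field stimulus kinematics (`generate_dot_stimulus`),
behavioural trial outcomes — vection presence, onset latency, duration,
0–10 strength with habituation drift (`generate_behaviour`) — and
64-channel, 1000 Hz EEG with 1/f background, amplitude-modulated alpha,
condition- and onset-locked alpha envelopes, theta/beta activity, button
artifacts and event markers (`generate_eeg_session`, `generate_cohort`).

**Behavioural statistics.** Wilcoxon rank-sum and signed-rank tests via
the continuity-corrected normal approximation with tie correction,
effect sizes r = Z/√N, Bonferroni screening of direction effects,
median-centred Spearman habituation analysis, and the boxplot-whisker
outlier rule (`compare_groups`, `compare_directions`,
`habituation_correlation`, `flag_outliers`).

**Spectral analysis.** Rotation periods are cut into non-overlapping 1-s
segments, segments containing button pushes or samples above 100 μV are
rejected, the rest are Hann-windowed and Fourier transformed, and each
electrode's spectrum is parameterized as an aperiodic 1/f component plus
Gaussian peaks, from which the individual band peak is extracted
(`segment_rotation_periods`, `reject_segments`, `compute_spectrum`,
`fit_spectral_model`, `extract_band_peak`).

**Permutation statistics.** Within-participant sign-flip shuffle tests
calibrated to Z values, with cluster-based multiple-comparison
correction: spatial clusters over the 10–10 electrode adjacency graph
and temporal clusters of at least 20 sequential time points, each tested
against max-cluster permutation nulls (`paired_shuffle_test`,
`spatial_cluster_test`, `temporal_cluster_test`). The cluster statistic
is the sum of member Z values.

**Time–frequency analysis.** Vection-onset-locked 8-s epochs from
eligible trials (≥3 s latency, ≥5 s ongoing vection), 7-cycle Morlet
decomposition over 3–40 Hz, per-participant decibel normalization
against the −2.5..−1.5 s pre-vection interval, and ROI alpha
time-courses with the −1.5..−0.5 s baseline and −0.5..+4 s vection
windows (`select_eligible_trials`, `extract_onset_epochs`, `morlet_tf`,
`db_normalize`, `roi_alpha_timecourse`).

**Orchestration.** `pipeline_config()` + `run_pipeline()` run the whole
chain on a simulated cohort (handedness groups analysed separately, the
temporal-test ROI taken from each group's significant spatial cluster),
with YAML config round-trip and plain-text session serialization.

## Worked example

```r
library(vectionEEG)

mon <- build_standard_montage()
mon
#> <electrode_montage> 64 channels (10-10), reference FCz
#>   adjacency: 107 edges, mean degree 3.34 (factor 1.30)

# one synthetic subject's behaviour under the study design
trials <- generate_behaviour(seed = 42)
summarize_subject(trials, "coherent")
#>   condition n_trials presence_pct median_onset_s median_duration_s
#> 1  coherent       50           98       5.688246          12.44156
#>   median_strength onset_defined
#> 1               5          TRUE

# group comparison of per-subject presence percentages
left  <- c(96, 98, 92, 96, 100, 94, 96, 98, 90, 96)
right <- c(94, 96, 90, 98, 92, 96, 94, 88, 96, 94)
compare_groups(left, right, n_obs = 10)
#> rank-sum test: Z = 1.321, p = 0.1864, r = 0.418 (n_obs = 10)

# spatial cluster test on a simulated 25-subject cohort with a 30%
# alpha-power drop injected at the left centro-parietal ROI
sim <- simulate_peak_power_cohort(25, mon, roi = roi_electrodes("left"),
                                  drop = 0.3, seed = 1)
cl <- spatial_cluster_test(sim$coherent, sim$incoherent, mon,
                           n_iter = 1000, seed = 2)
cl
#> <cluster_set> 4 cluster(s)
#> negative cluster: 7 members, mass -24.51, p = 0.000999
#> negative cluster: 1 members, mass -2.39, p = 0.5475
#> positive cluster: 1 members, mass 2.17, p = 0.8102
#> positive cluster: 1 members, mass 1.97, p = 0.9441
cl[[1]]$members
#> [1] "PO7" "CP1" "CP3" "P1"  "P3"  "P5"  "PO3"
```

The recovered significant negative cluster is exactly the seven
injected left centro-parietal electrodes; its p value of 1/1001 is the
floor of a 1000-iteration max-cluster null. The three single-electrode
clusters are chance supra-threshold electrodes that the cluster
correction correctly leaves non-significant.

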