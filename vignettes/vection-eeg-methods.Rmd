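---
title: "Methods: simulating and analysing EEG correlates of roll vection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing EEG correlates of roll vection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`vectionEEG` implements an analysis chain for EEG experiments on
visually induced self-motion perception (roll vection): condition
contrasts of spectral alpha power with spatial cluster-based permutation
correction, vection-onset-locked Morlet time–frequency analysis with
temporal cluster correction, and nonparametric behavioural statistics —
together with a synthetic session generator that emulates the
experimental design, since recordings of this kind are generally not
public. This vignette documents the generative model, the statistical
procedures, the tunable parameters, and the design decisions taken where
the methodology leaves choices open.

# The experimental design being emulated

A session consists of 12 practice trials followed by 100 main trials:
50 coherent (rigid rotation of 1000 dots at 30°/s in the roll plane) and
50 incoherent (per-dot randomized sinusoidal perturbation superimposed
on the same mean rotation), 25 per rotation direction (CW/CCW) within
each condition, presented in randomized blocks of 10. Each trial is a
jittered stationary period (3–5 s), 20 s of rotation, and 10 s of
stationary dots. Participants report vection onset/offset with
direction-specific buttons and rate vection strength 0–10 after each
trial. EEG is 64-channel (10–10 montage, reference FCz) at 1000 Hz.
`experiment_design()` encodes these values as defaults; reduced designs
(fewer trials, lower sampling rate) are accepted for simulation studies
and are what the test suite mostly uses.

# The synthetic data generator

## Stimulus kinematics

Coherent dots advance at exactly the signed design speed (CW is mapped
to negative angular velocity, CCW positive; `rotation_sign()`).
Incoherent dots add a sinusoidal perturbation to each dot's polar angle
(amplitude uniform 2–10°, frequency 0.2–1 Hz, phase uniform) and radius
(amplitude 0.01–0.05 disc radii), randomized per dot. Because a
sinusoid's contribution to the time-averaged angular velocity over 20 s
is bounded by amplitude/duration, the dot-averaged global velocity stays
within a few hundredths of a deg/s of the design speed; the acceptance
script measures this conservation property directly.

## Behaviour

Vection presence is Bernoulli per condition (defaults 0.95 coherent,
0.06 incoherent). Onset latency and duration are log-normal, truncated
so that onset < rotation end and offset ≤ rotation end (medians:
coherent ~5.8 s / ~12.8 s; incoherent ~11.7 s / ~4.5 s). Strength is a
rounded, clipped normal (coherent mean 5.3, SD 1.8) with a linear
habituation drift of 0.003 strength units per main trial, chosen so the
first-10 vs last-10 trial contrast is a few tenths of a point over 100
trials. These defaults target the behavioural group medians of the
study design loosely; no claim of distributional fidelity is made —
published reports typically give medians without dispersions, so the
shapes (log-normal, rounded normal) are conventional choices.

## EEG

Each channel is a sum of

* **1/f background**: spectrally shaped Gaussian noise with power
  ∝ f^(−χ), χ = 1.5 by default, scaled to 10 μV SD;
* **alpha** at the profile's individual peak frequency (default 10 Hz,
  7–14 Hz allowed): a sinusoid with random phase per trial and channel,
  multiplied by a slow stochastic amplitude modulation (depth 0.5,
  bandwidth < 0.75 Hz, power-normalized). The modulation gives the
  spectral peak a realistic 1–2 Hz width; a pure sinusoid would produce
  a one-bin line that no Gaussian parameterization can center stably;
* **condition envelope**: at the profile's ROI electrodes the alpha
  amplitude is multiplied by sqrt(1 − drop) throughout coherent rotation
  (default drop 0.3 of power);
* **onset-locked envelope**: on coherent trials with vection, a dip of
  −1.5 dB starting 0.5 s before the reported onset, and a sustained rise
  of +1 dB from 1.5 s after onset until vection offset (all four numbers
  per-profile parameters);
* **theta (5 Hz, 2 μV) and beta (25 Hz, 1 μV)** with no condition
  dependence, so that only the alpha band should ever test significant;
* **button artifacts**: 150 μV, 50 ms square pulses on all channels at
  every button event (configurable; 0 disables). The default amplitude
  deliberately exceeds the 100 μV rejection rule so the rejection logic
  is exercised.

Event markers (`motion_on`/`motion_off`/`vection_on`/`vection_off`) are
placed at the exact samples. With drop = 0 and zero onset-locked
parameters the generator is an exact null: conditions are exchangeable
at every channel, which the type-I-error tests rely on.

What the generator does *not* emulate: ocular and muscle artifacts and
their ICA residuals, volume conduction and channel covariance, alpha
nonstationarity beyond the modelled amplitude modulation, and any
direction (CW/CCW) asymmetry. Passing recovery tests therefore show the
analysis chain is correct and calibrated under this forward model — not
that it would behave identically on real recordings.

## Statistic-level simulators

For resampling studies where synthesizing raw EEG would be wasteful
(hundreds of cohorts), `simulate_peak_power_cohort()` draws
subject-by-electrode alpha peak-power matrices directly (log10-normal
between-subject spread 0.3, within-subject measurement noise 0.08,
multiplicative drop at the ROI), and `simulate_roi_trace_cohort()` draws
decibel ROI time-courses (temporally smoothed noise, SD 0.8 dB, with the
dip/rise shape). The full-EEG and statistic-level routes are both
exercised by tests; the heavy error-control studies run on the
statistic-level route.

# Analysis procedures

## Montage and adjacency

Electrode positions are idealized 10–10 coordinates on the unit sphere:
the ring through T7/T8/Oz at 90° inclination, the FT9/TP9/PO9 sub-ring
at 108°, midline anchors every 18°, and interior electrodes by
great-circle interpolation between the midline anchor and the same
row's ring electrode. Two electrodes are adjacent iff their chord
distance is at most 1.3 × the median nearest-neighbour distance of the
layout. Distances are evaluated **on the sphere**, not on the projected
disc: any disc projection stretches the outer ring tangentially
(~0.26–0.31 units against ~0.2 interior spacing), which under a planar
rule either isolates rim electrodes or over-connects the interior,
whereas the spherical arcs are nearly uniform (~18°). The resulting
graph is connected with mean degree ≈ 3.3; the factor is exposed
(`neighbour_factor`). Since the original cluster analysis did not state
its adjacency definition, cluster-membership comparisons against
published topographies are qualitative.

## Spectral chain

Rotation periods are segmented into non-overlapping 1-s windows
(half-open sample spans `[start, end)` everywhere). A segment is
rejected iff a button event falls in its span or any channel sample
exceeds 100 μV. Remaining segments are multiplied with a periodic Hann
window (periodic, so a sinusoid at a bin frequency is leakage-free) and
Fourier transformed; single-sided amplitude spectra are averaged per
channel. One-second segments give 1 Hz resolution.

The per-channel spectrum is then parameterized over 3–40 Hz as
log10-power = offset − exponent·log10(f) + Σ Gaussians:

1. robust aperiodic fit (two reweighting passes keeping the 60% of
   points with the smallest residuals — peaks only push residuals up);
2. greedy peak extraction from the flattened spectrum while the largest
   residual exceeds max(2 residual SDs, 0.05): each candidate's
   half-height width is measured on the shorter side (robust to
   neighbouring peaks), then refined by a windowed local Gaussian
   least-squares fit (raw half-width guesses are fragile under noise);
3. overlapping candidates pruned — the taller peak wins when centers
   are closer than the pair's larger bandwidth;
4. a joint box-constrained refit of all parameters (exponent in [0, 5],
   bandwidth in [0.3, 8] Hz, centers inside the fit range), dropping
   refitted peaks below the minimum height.

The band peak (theta 4–7, alpha 7–14, beta 20–30 Hz; lower edges
closed) is the tallest fitted Gaussian inside the band. The statistic
passed to the permutation tests is the **linear power of the raw
spectrum at the bin nearest the fitted center**, computed separately
per condition, electrode and participant — the closest literal reading
of testing "power at the individually defined peak"; the extractor is
isolated so height-above-aperiodic could be substituted. When no fitted
peak lies in a band the maximum raw in-band power is used and flagged
(`found = FALSE`), so no electrode is silently dropped.

## Permutation and cluster statistics

The elementary test is a within-participant sign-flip shuffle: observed
statistic = mean paired difference across participants (the simplest
statistic consistent with a generic "group test statistic"); the null is
built by flipping each participant's difference independently per
iteration (1000 by default); the observed value is converted to
Z = (obs − null mean)/null SD and to a two-sided normal p.

Spatial correction: electrodes with |Z| above the two-sided 0.05
threshold are joined into connected components over the montage
adjacency, separately per sign (same-sign clustering, matching the
standard cluster-permutation framework). Cluster mass is the sum of
member Z values. The null records, per iteration, the largest absolute
cluster mass after applying one subject-wise flip vector identically
across electrodes — preserving the spatial correlation structure — and
re-standardizing against the per-electrode null moments computed once
(avoiding nested permutation; the approximation is standard practice
and swappable). Cluster p = (1 + #{null ≥ |mass|})/(1 + n_iter), so p
is never exactly 0.

Temporal correction: each time point of the −0.5..+4 s vection window
is compared against the participant's scalar baseline (mean over
−1.5..−0.5 s); contiguous same-sign supra-threshold runs of ≥ 20 time
points form clusters; separate nulls of the largest positive and most
negative cluster mass are kept, and each observed cluster is tested
against its own sign's null. The 20-point rule applies on the analysis
grid actually used: the TF grid is the sampling grid by default, with
integer decimation (`decimate_by`) available for speed, and the grid is
recorded in the ROI trace (`grid_hz`).

For behavioural group contrasts, the rank-sum and signed-rank tests use
continuity-corrected normal approximations with mid-ranks and tie
corrections (the convention of the MATLAB statistics toolbox, whose
printed Z values this style of study reports). Effect sizes are
r = Z/√N with N = the per-group participant count by default: published
(Z, r) pairs of the form −1.25 → −0.25 are only consistent with N = 25
for 25-per-group designs; N is overridable. The package always reports
signed r. The Bonferroni family size for the direction screening is
passed explicitly (default 16 = 4 measures × 2 conditions × 2 groups)
because the screening family is a property of the analysis plan, not of
any single call.

## Time–frequency chain

Trials are eligible when vection onset is ≥ 3 s after motion onset and
vection persists ≥ 5 s. Epochs span −3..+5 s around onset (8 s exactly;
at 1000 Hz, 8000 samples). Because the onset button push sits at t = 0
of every epoch, the synthetic button artifact would contaminate the
pre-onset window; `repair_button_artifacts()` linearly interpolates the
known 50-ms pulse windows (plus 10 ms guards) before epoching. This is
the package's minimal stand-in for the artifact-cleaning stage of real
preprocessing pipelines, exact on synthetic data where the pulse is the
only modelled artifact.

The Morlet transform uses 7-cycle complex wavelets on 3–40 Hz in 1 Hz
steps, implemented as Gaussian analytic filters in the frequency domain
with peak gain 1 at the center frequency; epochs are padded by
reflection and the edge margin of half a wavelet length per side
(cycles/2/f seconds) is reported per frequency. All analysis windows lie
at least 0.5 s inside the epoch, so the default windows are unaffected
by edge contamination.

Linear power is averaged across trials per participant *before* decibel
conversion (the normalization is per participant); dB = 10·log10 of
power relative to the mean over the −2.5..−1.5 s pre-vection interval,
computed per frequency (the standard choice where the original text is
silent). A map can be normalized only once — re-normalization is an
error, never a silent double conversion. ROI alpha time-courses average
dB over the ROI channels and the 7–14 Hz wavelet frequencies; the ROI
sets are the left centro-parietal seven (CP1, P3, CP3, P1, P5, PO7,
PO3) and the midline five (Pz, CP2, P1, P2, CPz), available via
`roi_electrodes()`. In `run_pipeline()` each handedness group's
temporal-test ROI is taken from its significant negative spatial
cluster when one exists, else from the group profile's default.

# Numerical and interface conventions

* Half-open `[start, end)` spans for segments and windows; a button
  event exactly on a boundary belongs to the following segment.
* Seeds: every stochastic routine takes a seed and records it in its
  result; cohort generation derives per-subject seeds from the master
  seed by a fixed affine map kept inside the 32-bit integer range, so
  cohorts are reproducible element by element.
* Degenerate inputs take defined paths, not errors: all-zero paired
  differences give Z = 0, p = 1 with a `degenerate` flag; constant
  pooled strengths flag the Spearman result; no supra-threshold
  electrode yields an empty cluster list.
* Sessions serialize to a plain-text bundle (data/events/trials/buttons
  TSV + YAML metadata) with validation on read (0–10 strength range,
  sorted events, dimension checks against metadata); configs serialize
  to YAML and round-trip losslessly.

# Test-suite problem sizes

The generators default to the full study design; the suite runs them at
reduced scale as its own choice of simulation size: sessions of 8–20
trials at 200–250 Hz for the full-EEG paths (with two trials at the
full 1000 Hz design to pin the 20 × 1000-sample segmentation and
8000-sample epochs), 10-subject cohorts for the injected-effect
recovery of the 0.7 coherent/incoherent ROI power ratio, and
statistic-level cohorts of 25 subjects for error control (200 null
cohorts for the family-wise error rate of the spatial cluster test) and
for the 20-cohort spatial and temporal recovery studies.

# Known limitations

* The adjacency rule, though standard in kind, is not the (unpublished)
  one used in the original cluster analyses; electrode-level cluster
  membership should be compared qualitatively.
* The spatial null re-standardizes per-iteration maps against fixed
  per-electrode null moments instead of nested permutation; this is the
  usual cost-saving approximation and is documented as swappable.
* The generator's alpha model (modulated sinusoid) captures band power
  and its envelopes, not waveform asymmetries or cross-frequency
  structure; channels are independent apart from shared envelopes, so
  spatial correlation of real EEG is under-represented — cluster-size
  distributions on real data will differ.
* Session serialization is a documented text bundle, not a clinical
  interchange format.
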