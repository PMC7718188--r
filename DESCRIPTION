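Package: vectionEEG
Title: Simulation and Analysis of EEG Alpha-Band Correlates of Visually
    Induced Self-Motion Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse 64-channel EEG experiments on
    visually induced self-motion perception (vection) under optokinetic
    roll stimulation. Provides a synthetic session generator (dot-field
    stimulus kinematics, behavioural trial outcomes, multichannel EEG with
    1/f background and condition-dependent alpha oscillations),
    nonparametric behavioural statistics with rank-based effect sizes,
    Hann-windowed FFT spectra with aperiodic (1/f) plus Gaussian peak
    parameterization, within-participant permutation tests with spatial
    (electrode-adjacency) and temporal (run-length) cluster-based
    multiple-comparison correction, and Morlet wavelet time-frequency
    analysis locked to vection onset with decibel baseline normalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
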