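Package: meaburst
Title: Inhibition Analysis of Cultured Cortical Networks on Microelectrode Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of extracellular recordings from cultured
    cortical networks on planar microelectrode arrays (MEAs) under inhibitory
    treatments. Provides a seeded synthetic-data generator for network
    bursting activity and raw waveform-level recordings, precision timing
    spike detection (PTSD) with robust noise estimation, logISI burst
    detection with network-burst labelling, the standard burst/spike metric
    panel (MBR, MSR, IBI, BD, IBSR) with baseline normalisation, channel
    synchrony (CV) and spatial-variability (normalised RMSE) statistics,
    binned rate time courses with initial inhibitory rate and
    post-inhibitory rebound quantification, spike sorting and action
    potential waveform-feature analysis, four-parameter logistic
    dose-response fitting, and nonparametric multi-group comparison
    (Kruskal-Wallis, Conover post-hoc, epsilon-squared, compact letters).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    minpack.lm,
    mclust,
    data.table,
    jsonlite,
    rhdf5
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
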