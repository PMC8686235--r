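Package: hotspotr
Title: EEG-Based Motor Hotspot Localization from Band-Power Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Localizes the primary motor cortex "hotspot" from scalp EEG.
    Implements the full analysis pipeline: preprocessing of multichannel
    press-locked recordings (downsampling, common average reference,
    zero-phase Butterworth band-pass, ICA-based artifact removal, epoching),
    per-trial FFT power spectral density features in canonical frequency
    bands, a shallow neural-network regressor of 3D hotspot coordinates
    with subject-stratified tenfold cross-validation, and an evaluation
    layer (Euclidean error distances, repeated-measures ANOVA with
    Bonferroni-corrected post-hocs, paired t-tests, movement-related
    potential characterization). Ships a seeded synthetic motor-EEG cohort
    generator with known ground-truth hotspots for validation, electrode
    montage utilities for the extended 10-20 system, and readers/writers
    for BrainVision-style recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
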