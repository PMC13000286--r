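Package: napstat
Title: Nap EEG/ECG and Dream-Report Analysis with Permutation-Corrected
    Correlation Topographies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for daytime-nap studies that relate sleep
    physiology and dream content to behavioral score gains. Includes a
    seeded synthetic-cohort generator (stage-structured EEG with planted
    slow waves, spindles and artifacts; modulated ECG; rater Likert forms;
    game scores), a ten-step EEG cleaning pipeline (average re-reference,
    filtering, line-noise regression, two-pass bad-channel rejection,
    FastICA ocular removal, amplitude and normalized-power artifact
    masking, spherical-spline interpolation), band-power spectra from
    artifact-free 2-s segments, slow-wave and A7-style spindle detection
    stratified by hypnogram stage, Pan-Tompkins beat detection with
    automated inter-beat cleaning and 11 heart-rate-variability metrics,
    rater-consensus dream properties with intraclass correlation, game
    scores and experience covariates, and Spearman and partial Spearman
    correlation families with max-statistic permutation adjustment.
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
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
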