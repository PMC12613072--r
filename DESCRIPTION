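Package: catrace
Title: Calcium Imaging Analysis for Organoid Two-Photon Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A tidy pipeline for two-photon calcium imaging of neural
    organoids: rigid motion correction by cross-correlation, seeded
    region-of-interest growing and trace extraction, Savitzky-Golay
    smoothing, baseline (F0) estimation with a sliding-window low
    percentile filter, deltaF/F0 computation, Ca2+ event detection with
    findpeaks-compatible height/width/distance criteria, three-criterion
    active-cell classification (skewness, SD, event count), and cohort
    summaries with Student's t, Tukey and Dunnett comparisons.  Includes
    a synthetic-recording generator with exact ground truth (event
    schedules, amplitudes, motion shifts, activity labels) so every
    stage of the pipeline can be validated without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    multcomp,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
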