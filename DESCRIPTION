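Package: motorpheno
Title: Motor Phenotyping and Cell-Type Attrition Analysis for Parkinsonian Mouse Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies progressive motor deficits and dopaminergic cell-type
    attrition in longitudinal mouse cohorts. Provides accelerometer-based
    tremor quantification (zero-phase Butterworth gravity separation, body
    acceleration, short-time Fourier spectrograms of the dorso-ventral axis
    with per-window 0-1 normalization, and 12-18 Hz band-power summaries with
    optional immobility gating), pose-tracking kinematics (likelihood
    filtering, speed, immobility-bout segmentation, locomotion metrics,
    stop/move duration densities, rearing detection), mixed-effects logistic
    differential cell-type abundance with Benjamini-Hochberg FDR control,
    group-comparison statistics, and tracing input/output fraction tables.
    Includes seeded synthetic-data generators for all input families so every
    analysis stage can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
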