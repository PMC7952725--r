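Package: emgvalence
Title: Facial EMG Preprocessing and Subjective Valence Concordance Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing subjective emotional valence from facial
    electromyography (EMG) recorded over the corrugator supercilii and
    zygomatic major muscles. Implements device-specific signal conditioning
    (zero-phase 20 Hz high-pass filtering, 51-point moving-average drift
    subtraction, rectification, epoching with artifact excision, baseline
    correction, 1-s binning and within-individual standardization), a
    maximum-likelihood linear mixed-effects concordance model with random
    by-participant slopes and intercepts and m - l - 1 degrees-of-freedom
    one-tailed slope tests, standardized-residual outlier refitting, lagged
    correlation utilities, rating-scale analyses (one-sample tests against
    the neutral midpoint, on-line versus cued-recall validation, noncentral-t
    sample-size search), and a synthetic-data generator with known
    ground-truth coupling that emulates film-viewing and motion-game
    recording sessions for wired (1000 Hz) and wearable (500 Hz) devices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    jsonlite,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
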