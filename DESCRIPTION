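Package: fedseizr
Title: Federated EEG Preictal-State Prediction with Spiking Graph Networks and Fuzzy Risk Staging
Version: 0.1.0
Authors@R:
    person("fedseizr", "developers", email = "fedseizr@example.org", role = c("aut", "cre"))
Description: A patient-specific epileptic seizure prediction pipeline for
    multichannel scalp EEG. Provides preprocessing (zero-phase Butterworth
    bandpass filtering, per-second z-score normalization, design-of-experiments
    wrapper channel selection), multi-timescale segmentation with balanced
    sample generation and ROC-based bi-timescale selection, a threshold spiking
    encoder with a seizure-indicator rule and surrogate gradients, a spiking
    graph-convolutional classifier over the channel correlation graph,
    simulated cross-hospital federated averaging with Bregman-divergence
    regularized personalization, Sugeno ANFIS risk staging tuned by particle
    swarm optimization over EEG probability, heart-rate-variability features
    and clinical records, and evaluation utilities (sensitivity, specificity,
    FPR, AUC, relative accuracy, leave-one-subject-out cross-validation).
    Ships a seeded multi-hospital synthetic data generator so the full
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
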