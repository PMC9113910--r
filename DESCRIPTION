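Package: phnalff
Title: Resting-State ALFF/f-ALFF Mapping, Cluster Statistics, Autoencoder
    Feature Extraction and Treatment-Efficacy Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end computational pipeline for evaluating analgesic
    efficacy in postherpetic neuralgia from resting-state functional MRI
    and clinical follow-up. Computes voxel-wise amplitude of low-frequency
    fluctuation (ALFF) and fractional ALFF maps from 4D BOLD volumes
    (initial-volume discard, linear detrending, Gaussian spatial smoothing,
    0.02-0.07 Hz band), performs voxel-wise two-sample and paired t tests
    with cluster-extent thresholding and atlas labelling, implements a
    stacked autoencoder with softmax head for raw-versus-fine feature
    classifier comparisons (linear SVM, RBF SVM, softmax), and scores
    clinical response from visual analog scale trajectories (VAS weighted
    value, outcome categories, total effective rate). Includes a seeded
    synthetic-data generator (band-limited BOLD simulator with planted
    group-difference regions, clinical tables, feature matrices) so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
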