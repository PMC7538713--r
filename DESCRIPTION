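Package: eegmdd
Title: Interhemispheric Asymmetry and Cross-Correlation Features for
    EEG-Based Depression Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for detecting major depressive disorder
    (MDD) from resting-state EEG. Implements mastoid re-referencing,
    zero-phase FIR band-pass filtering, non-overlapping epoch
    segmentation, Welch band-power estimation in the theta, alpha and
    beta bands, interhemispheric log-power asymmetry and min-max
    normalized cross-correlation features over 28 symmetric electrode
    pairs, additive/subtractive feature fusion (MIX1/MIX2), 7x4xL
    spatial feature tensors, group-level one-way ANOVA significance
    maps, and three classifiers (KNN, polynomial-kernel SVM, and a
    small convolutional network) evaluated by repeated shuffled 10-fold
    cross-validation. Includes a synthetic two-cohort EEG generator
    with controllable band-specific hemispheric asymmetry and
    symmetric-pair coupling, plus EDF read/write, so the full pipeline
    is testable without clinical recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    class,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cnn.R'
    'classify.R'
    'registry.R'
    'edf.R'
    'eegmdd-package.R'
    'spectral.R'
    'features.R'
    'stats.R'
    'preprocess.R'
    'synthetic.R'
    'pipeline.R'
    'utils.R'
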