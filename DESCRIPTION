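Package: eegmci
Title: EEG Discriminant Framework for Progression from Amnestic Mild
    Cognitive Impairment to Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resting-state EEG analysis pipeline for separating amnestic
    mild cognitive impairment (aMCI) patients who progress to Alzheimer's
    disease (PMCI) from those who remain stable (SMCI). Implements the full
    chain: a two-group synthetic EEG cohort generator, preprocessing
    (average reference, zero-phase FIR band-pass and notch filtering,
    down-sampling, epoch segmentation), spectral features (Welch band-power
    ratios, spectral entropy, interhemispheric asymmetry), nonlinear
    features (multiscale permutation/approximate/sample entropy, Lempel-Ziv
    complexity, Hurst exponent, and the median distance from the centroid
    of the phase-space reconstruction), per-band functional connectivity
    (Pearson correlation, phase lag index, magnitude-squared coherence),
    and leakage-safe subject-level 10-fold cross-validated classification
    with train-fold-only feature selection, standardization and PCA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    MASS,
    class,
    e1071,
    rpart,
    randomForest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
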