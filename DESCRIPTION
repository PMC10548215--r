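Package: canopyspec
Title: Canopy Hyperspectral Reflectance as a Surrogate for Leaf Physiology in Rice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline relating automated canopy-level hyperspectral
    imaging to leaf-level physiology in diverse rice. Calibrates raw digital
    numbers to percent reflectance against white and dark references, averages
    imaging events to weekly and accession-mean spectra, reproduces the
    multivariate ground-reference analyses (trait derivation, transforms,
    Pearson correlations with mean imputation, correlation-matrix PCA,
    average-linkage clustering), selects wavelengths by covariance-PCA loadings
    (for support vector machine treatment classification with rough/fine
    exponential grid search and cross-week evaluation) and by the RReliefF
    regression estimator (for orthogonal-scores partial least squares trait
    prediction with leave-one-out component selection, jackknife prediction
    intervals, and transfer and hyperparameter-grid experiments). A synthetic
    experiment generator emulates the study design (23 accessions from two
    subpopulations, two nitrogen levels, 94 pots, four imaging weeks) so the
    full pipeline is testable without the archived imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    yaml
Config/testthat/edition: 3
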