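Package: dyadconcord
Title: Trial-Wise Brain-to-Brain Concordance Analysis for fMRI Hyperscanning Dyads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-person (hyperscanning) fMRI experiments
    in which a patient and a clinician are scanned simultaneously during a
    block-design pain-treatment protocol. Provides a synthetic dyad generator
    with known ground-truth coupling, double-gamma HRF design matrices
    (condition-wise and one-regressor-per-trial), AR(1) prewhitened GLM
    estimation with contrasts, fixed-effects averaging, group models,
    minimum-statistic conjunction, Benjamini-Hochberg FDR and sign-flip
    permutation cluster correction, trial-wise ROI beta-series extraction and
    dyadic concordance regression with clinical-context contrasts, behavioral
    statistics (analgesia scores, paired TOST equivalence tests, rating
    correspondence, facial-expression mirroring), and percentile-bootstrap
    mediation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
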