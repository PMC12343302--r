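Package: prognoselect
Title: Precision-Optimised Selective Prognosis for Post-Stroke Aphasia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selective classification pipeline for predicting binary language
    outcomes after stroke from lesion-load and demographic predictors. Fits
    random under-sampling boosted (RUSBoost) decision-tree ensembles for
    imbalanced outcomes, tunes per-class score thresholds on a validation
    split to maximise positive and negative predictive value so that only
    high-confidence classifications are issued, and evaluates the resulting
    confidence/coverage trade-off by repeated nested cross-validation.
    Includes a synthetic cohort generator with a latent predictability
    mixture, lesion-load feature extraction from NIfTI images against an
    atlas parcellation, and the post-hoc group-comparison statistics
    (Wilcoxon rank-sum, two-proportion z) used to characterise the
    'predictable' subgroup.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
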