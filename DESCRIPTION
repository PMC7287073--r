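Package: priorselect
Title: Prior-Knowledge and Data-Driven Feature Selection for Drug
    Sensitivity Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-drug predictive modeling of cancer cell-line drug
    sensitivity (dose-response AUC) from multi-omic features, comparing
    biologically driven feature sets (drug targets, target-pathway genes,
    gene-expression signatures) against genome-wide expression with and
    without automatic feature selection (stability selection, random
    forest importance). Includes gene-signature coherence scoring and
    activity scores, elastic net and random forest models under a
    repeated train/test split protocol, a relative-RMSE evaluation
    against a training-mean dummy baseline, pathway-level model
    comparisons, and a synthetic multi-omic data generator with planted
    response mechanisms for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    ranger,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
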