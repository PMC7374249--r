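Package: tolsig
Title: Drug-Adjusted Gene-Expression Signatures of Operational Tolerance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Development and evaluation of RT-qPCR gene-expression signatures of
    operational tolerance in kidney transplant recipients. Expression on the -dCt
    (log2 relative) scale is statistically adjusted for immunosuppressive drug
    therapy ("in-silico drug withdrawal") by per-gene linear residualization before
    signature calibration with elastic-net penalized logistic regression inside
    repeated stratified cross-validation. Final signatures are median-coefficient
    aggregates of the cross-validation ensemble; a consensus gene set is obtained
    by retention-frequency selection under a lasso-leaning penalty. Includes
    preprocessing (delta-Ct computation, QC, outlier recoding, k-nearest-neighbour
    imputation), a DeLong ROC and Cohen's kappa evaluation battery, and a synthetic
    clinical-cohort generator for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    e1071,
    optparse
Config/testthat/edition: 3
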