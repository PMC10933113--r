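Package: qhtsSkinSens
Title: Quantitative HTS Pipeline for Skin Sensitization Defined Approaches
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing quantitative high-throughput screening (qHTS)
    data for skin sensitization hazard and potency assessment. Implements
    plate-signal normalization against DMSO vehicle controls, four-parameter
    Hill concentration-response fitting with curve classification and curve
    ranks, per-assay positive/negative calls under OECD test-guideline and
    curve-rank criteria (KeratinoSens, DPRA, hCLAT, IL-8), the 2-out-of-3,
    ITSv2 and STS defined approaches with GHS potency categorization and
    concordance analytics, chemotype-based compound prioritization, and a
    QSAR modeling grid over binary chemotype fingerprints (feature selection,
    class rebalancing, five classifier families, repeated cross-validation).
    A synthetic-data module generates dose-response plates, assay-call panels
    and fingerprint matrices with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    e1071,
    randomForest,
    nnet,
    xgboost,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
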