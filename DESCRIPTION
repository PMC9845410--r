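Package: qsarstack
Title: Dual-Screening QSAR Pipeline with Stacked Regression and Voting
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end quantitative structure-activity relationship
    (QSAR) workflow for wide molecular-descriptor tables: cleaning
    (near-null column elimination, Kolmogorov-Smirnov normality scan,
    iterated box-plot fence winsorization, min-max scaling), descriptor
    ranking by a dual grey-relational / Spearman weighted screening score,
    stacked ensemble regression of ER-alpha bioactivity (pIC50) with
    out-of-fold meta learning, and dual-route feature-selection voting
    classifiers for binary ADMET endpoints, together with a seedable
    synthetic-data generator that emulates the statistical structure of
    anti-breast-cancer candidate descriptor tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    randomForest,
    ranger,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
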