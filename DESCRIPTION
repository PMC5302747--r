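Package: radmark
Title: Serum Proteome Marker Discovery for Radiation-Induced Skin Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible re-implementation of a serum-proteome marker
    discovery pipeline for cutaneous radiation syndrome in the mouse.
    Simulates 2D-DIGE spot matrices and SELDI-TOF spectra with the study's
    dose-by-day design (0/20/40/80 Gy, days 3 and 7), preprocesses spectra
    (baseline subtraction, total-ion-current normalization, peak detection,
    two-pass cluster completion), runs per-feature ANOVA, signed fold
    changes, Monte-Carlo permutation tests and Benjamini-Yekutieli FDR
    control, performs PLS-DA VIP and Random-Forest importance-frequency
    stability selection, and scores candidate panels with stepwise LDA,
    stepwise-AIC logistic regression, confusion matrices, ROC/AUC and PCA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    tools,
    MASS,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mixOmics,
    yaml
Config/testthat/edition: 3
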