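Package: qdelta
Title: Voxel-Based Normalized-Enhancement Quantification and Imaging
    Subtypes of Pancreatic Cancer on Multiphase CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies pancreatic ductal adenocarcinoma (PDAC) tumor
    enhancement on co-registered multiphase (pancreatic-protocol) CT:
    voxel-wise normalized enhancement (NE) relative to normal pancreatic
    parenchyma and anterior abdominal fat reference regions, the nAUC
    transport ratio, and an 8-level enhancement heterogeneity map. Builds
    the q-delta logistic classifier of imaging subtypes (univariate
    screens, backward elimination, multivariate fit, ROC with DeLong
    intervals), rater-agreement metrics (Dice similarity, two-way
    absolute-agreement intraclass correlation), and outcome-association
    statistics (Kaplan-Meier/log-rank, Cox proportional hazards, Fisher
    exact tests with relative risk, Spearman correlation, Welch t-test).
    Includes seeded generators for multiphase CT phantoms, rater-perturbed
    contours and synthetic patient cohorts so the full pipeline can be
    exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    pROC,
    RNifti,
    stats,
    survival,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
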