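Package: npxburden
Title: Differential Analysis, Disease-Burden Model Selection and Composite
    Scoring for Targeted Plasma Proteomics (NPX)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for targeted plasma-proteomics panels
    reported on the log2 Normalized Protein eXpression (NPX) scale, built
    around a four-group case/control design (comorbid PTSD-MCI, PTSD only,
    MCI only, unaffected controls). Provides limit-of-detection imputation,
    bridging-sample batch correction and technical-duplicate QC;
    per-protein covariate-adjusted linear models with within-panel
    Benjamini-Hochberg FDR; Monte-Carlo split-half replication; BIC
    selection among competing disease-burden group codings; and
    elastic-net multiprotein composite scores evaluated by leave-one-out
    AUC and symptom-severity correlations. Includes a synthetic-data
    generator emulating the study design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
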