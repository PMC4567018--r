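Package: lungscore
Title: Additive Prognostic Scoring for Non-Small Cell Lung Cancer Survival
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Construction and internal validation of an additive prognostic
    scoring system for overall survival in non-small cell lung cancer.
    Provides cohort ingestion and factor coding, self-contained
    Kaplan-Meier, log-rank and Cox proportional-hazards estimation
    (Breslow and Efron tie handling), conversion of per-level 5-year
    survival rates into integer scores, total-score stratification into
    survival categories, bootstrap validation of model selection and of
    per-level rates, and a synthetic cohort generator with configurable
    covariate marginals and proportional-hazards effects so the whole
    pipeline can be exercised without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
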