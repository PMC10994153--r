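Package: ogttfda
Title: Functional Data Analysis of Oral Glucose Tolerance Test Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing five-timepoint oral glucose tolerance test
    (OGTT) glucose and insulin responses in pediatric cohorts. Each
    participant's sampled trajectory is smoothed with a penalized cubic
    B-spline basis, summarised by functional principal component (FPC)
    scores, and classified into the classical biphasic, monophasic and
    monotonically increasing curve shapes. The package provides
    cross-sectional association testing of curve features against metabolic
    health parameters, longitudinal prediction of dysglycemia from seven
    competing predictor sets with ROC/AUC comparison, and a seeded synthetic
    cohort generator that reproduces the statistical structure the analysis
    assumes, so the full pipeline is testable without restricted clinical
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
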