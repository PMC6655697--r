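Package: smrprofiler
Title: Risk-Adjusted Hospital Mortality Profiling from Paired Clinical
    and Administrative Registries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing the completeness of a voluntary clinical
    surgical registry against an exhaustive administrative reference,
    classifying hospitals by data quality, building case-mix logistic
    risk-adjustment models (with multiple imputation for missing lung
    function and explicit missing-data categories for pathological
    staging), computing standardized mortality ratios under an
    internally fitted model and under a transferred reference model,
    flagging mortality outliers, and quantifying agreement between the
    two profiling routes with Cohen's kappa.  A synthetic two-registry
    generator with a known true mortality model and configurable
    hospital-level under-reporting mechanisms provides ground truth for
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    dplyr,
    tibble,
    rlang,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
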