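Package: vaval
Title: Validation of Verbal Autopsy Cause-of-Death Interpretation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating verbal autopsy (VA) interpretation methods
    against a gold-standard cause of death. Implements a Bayesian
    successive-indicator cause-of-death assignment engine in the style of
    InterVA (up to three likely causes per death, prevalence-adjusted priors,
    indeterminate fallback), recoding of fine-grained cause labels onto a
    condensed common cause list, and the agreement statistics used in VA
    validation studies: cause-specific mortality fractions (CSMF), Cohen's and
    Fleiss' kappa with confidence intervals, per-cause sensitivity,
    specificity, PPV and NPV with exact binomial intervals, and ROC curves
    with trapezoidal AUC. A synthetic-cohort simulator generates deaths with
    known true causes, cause-conditional indicators and imperfect categorical
    raters so the full pipeline can be exercised end to end without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
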