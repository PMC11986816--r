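Package: fairscreen
Title: Fairness-Aware Risk-Based Cancer Screening Eligibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and evaluating fairness-aware screening
    eligibility mechanisms on imbalanced cohort data. Implements
    intersectional reweighing as a pre-processing bias mitigation step,
    an easy-ensemble classifier (balanced random under-sampling combined
    with adaptive boosting) alongside a weighted logistic baseline,
    post-processing eligibility thresholds (specificity-matched and
    Youden-index), rule-based USPSTF 2013/2021 comparators, and a full
    statistical evaluation protocol: per-group error rates, equal
    opportunity differences, paired t-tests with Hedges' g and
    common-language effect sizes, McNemar's test, DeLong's test for
    correlated AUCs, stratified bootstrap confidence intervals and a
    Monte-Carlo Kolmogorov-Smirnov normality check. A seeded synthetic
    cohort generator emulates the class and group imbalance of large
    lung-screening trials so the whole pipeline can be exercised
    end-to-end without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
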