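Package: thyropls
Title: Paired Biomarker Analysis and Two-Block PLS for Selenium
    Supplementation Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for paired (pre/post supplementation)
    biomarker cohorts in autoimmune thyroiditis: distribution-screened
    paired testing with automatic Student-t/Wilcoxon routing and log-scale
    summaries for skewed biomarkers; a from-scratch two-block NIPALS
    partial least squares engine with Q2 (PRESS-based) cross-validation,
    component retention and iterative pruning of uninformative parameters;
    a correlation-weight statistic on the two-component weight plot with
    Spearman rank cross-checks; and a latent-factor synthetic cohort
    generator that reproduces the marginal distributions and rank
    correlation structure such studies report, so the whole pipeline is
    testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
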