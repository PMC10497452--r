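Package: volagree
Title: Reliability and Agreement Analysis for Multi-Scanner Brain Volumetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-sectional test-retest reliability analysis for regional
    brain volume measurements acquired on multiple MR scanners, as used in
    scan-rescan studies of people with multiple sclerosis. Provides
    single-measurement intraclass correlation coefficients for absolute
    agreement and consistency with F-based 95% confidence intervals, crossed
    variance-component decomposition (subject, scanner, subject-by-scanner,
    residual), standard error of measurement and smallest detectable change
    as percentages of the mean, repeated-measures ANOVA and Friedman tests of
    systematic scanner bias with Bonferroni-corrected post-hocs,
    Bland-Altman agreement statistics, and two-sample power planning that
    contrasts within-scanner with between-scanner measurement variance. A
    synthetic cohort generator reproduces the statistical structure of a
    21-subject, three-scanner, scan-rescan design so that every stage of the
    pipeline is testable without access to patient data.
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
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
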