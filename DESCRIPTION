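Package: volagree
Title: Multi-Observer Agreement Analysis for Tumor Volumetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inter-observer agreement analysis for volumetric annotations of
    vestibular schwannoma (and other tumors) measured by several observers.
    Implements the limits of agreement with the mean (LOAM) with a two-way
    ANOVA variance decomposition and modified large-sample confidence
    intervals, the intraclass correlation coefficient with F-based intervals,
    volume-quartile stratification with cyst-exclusion sensitivity analysis,
    a sliding-window volume-dependent agreement curve with growth-cutoff
    lookup, covariate regression of the relative volume standard deviation,
    the confidence-interval lower-limit (assurance) sample-size procedure for
    reliability studies, and a calibrated synthetic multi-observer cohort
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    ggplot2,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
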