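Package: smartats
Title: Design and Analysis of Sequential Multiple Assignment Randomized Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing and analyzing sequential multiple assignment
    randomized trials (SMARTs) that compare adaptive treatment strategies.
    Provides sample-size calculation based on a noncentral chi-squared global
    test or on pairwise tests, enumeration of the strategies embedded in a
    two-stage design (including degenerate branches), strategy-value estimation
    by G-computation or inverse-probability weighting with the induced singular
    covariance, a generalized-inverse Wald global test with Bonferroni
    simultaneous confidence intervals for pairwise comparisons, sequence-level
    descriptive statistics, design/summary/forest plots, and a seeded trial
    simulator for operating characteristics.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    ggplot2,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
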