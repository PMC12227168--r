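Package: qmctp
Title: Quantile-Based Multiple Contrast Tests and Simultaneous Confidence Intervals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous tests and confidence intervals for linear contrasts
    of group quantiles (medians, interquartile ranges, and joint median/IQR
    comparisons) in one-way layouts with possibly skewed, heavy-tailed and
    heteroskedastic data. Supports two-sided, noninferiority and equivalence
    (TOST) hypotheses with Dunnett-, Tukey- and grand-mean-type contrast
    families, three estimators of the asymptotic covariance of sample
    quantiles (kernel, groupwise bootstrap, order-statistic interval), and
    four critical-value procedures: Bonferroni-adjusted asymptotic and
    studentized permutation tests, and asymptotic and groupwise-bootstrap
    multiple contrast test procedures (max-t tests). Includes a simulation
    engine for family-wise error rate and power studies under a
    location-scale model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
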