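Package: lbmpe
Title: Lean Body Mass Prediction Equations and Method-Comparison Statistics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Anthropometric and biochemistry-based prediction equations for
    lean body mass (LBM), together with the complete machinery used to develop
    and validate such equations against dual-energy X-ray absorptiometry (DXA):
    exhaustive best-subset ordinary-least-squares regression ranked by adjusted
    R-squared, Lin's concordance correlation coefficient with bias-correction
    factor, Bland-Altman 95% limits of agreement, and Sheiner-Beal mean error
    and root-mean-square error with confidence intervals. Includes built-in
    coefficient sets for four developed LBM equations and the published
    Heitmann, Janmahasatian and Deurenberg fat-free-mass comparators, cohort
    file input/output with validation and sex/age/BMI stratification, a
    synthetic-cohort generator with truncated-normal marginals for fully
    reproducible develop-validate-stratify workflows, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
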