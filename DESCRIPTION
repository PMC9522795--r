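Package: lungage
Title: Spirometry-Derived Lung Age Estimation and Normal Limits
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation of lung age from spirometry by backward age
    regression in healthy never-smokers.  Fits sex-specific multiple
    linear, continuous piecewise-linear and natural-cubic-spline models
    of chronological age on spirometric indices (FEV1, FEF50, FEF75,
    MMEF, FVC) and height, selects among candidate models by adjusted
    R-squared, and validates them by bootstrap resampling.  Derives
    age-dependent and constant upper limits of normal for the difference
    between lung age and chronological age, classifies individuals
    against those limits, assigns GOLD-style airflow-limitation stages,
    applies healthy-subject inclusion filters, balances patient and
    healthy cohorts by propensity score matching, and generates
    calibrated synthetic healthy, COPD and asthma cohorts so the whole
    pipeline can be exercised without access to clinical databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    splines,
    withr
Config/testthat/edition: 3
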