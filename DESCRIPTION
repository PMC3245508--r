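Package: actflm
Title: Functional Linear Modeling of Circadian Actigraphy Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analyse minute-epoch wrist actigraphy as functional data:
    weekday selection and averaging into 1440-minute circadian profiles,
    Fourier-basis least-squares smoothing into circadian activity curves,
    function-on-scalar regression of activity curves on scalar clinical
    covariates (e.g. apnea severity, body mass index), a pointwise F
    statistic with permutation-based global and pointwise significance,
    pointwise confidence bands for group mean curves, a synthetic cohort
    generator with known circadian truth for end-to-end validation, and
    publication-style figures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    patchwork,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
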