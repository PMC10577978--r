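Package: wellmix
Title: Private Well Water Metal Mixtures and Preterm Birth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for linking census-tract private-well metal concentrations
    to preterm birth. Implements left-censored (Tobit) regression embedded in
    a chained-equations imputation loop for concentrations below the limit of
    reporting, tract-level exposure construction with percentile and
    maximum-contaminant-level exceedance codings, crude and adjusted
    single-metal logistic odds-ratio tables, and quantile-based g-computation
    for exposure mixtures, including sample-splitting partial effects and
    effect-measure modification by categorical strata. A synthetic-data
    generator with known ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    withr,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
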