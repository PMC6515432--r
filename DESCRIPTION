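Package: caflux
Title: Calcium Trace Activity Metrics and Phenotype Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-cell calcium imaging of embryonic
    cells: contiguity filtering and asymmetric-least-squares detrending of
    per-cell fluorescence traces; four per-cell activity metrics
    (multi-threshold spike frequency, average power, rescaled-range Hurst
    exponent, Markovian entropy); plate-normalized FISH expression scores and
    positivity calls; effect-size-gated nonparametric comparison of activity
    between phenotype-defined cell populations with shuffle and
    label-randomization controls; and a seeded synthetic-data generator
    (fractional Gaussian noise plus Poisson spike trains) with known ground
    truth for validating every stage.
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
    Matrix,
    mgcv,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
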