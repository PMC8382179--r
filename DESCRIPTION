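Package: wingsense
Title: Sparse Neural-Inspired Strain Sensing on Flapping Flexible Wings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates spatiotemporal strain on a flapping, flexible insect
    wing undergoing body rotation (assumed-modes Kirchhoff plate in a rotating
    frame), encodes strain with probabilistic linear-nonlinear spiking sensors,
    selects a sparse optimal sensor subset by sparse sensor placement
    optimization for classification (SSPOC, elastic-net recovery of a
    discriminant projection), and classifies rotation condition from
    single-spike timing per wingbeat. Includes parameter-sweep, sensor-dropout
    and disturbance-robustness experiment drivers with seeded, reproducible
    outputs, plus broom-style tidiers and ggplot2 autoplot methods for the
    result types.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    jsonlite,
    readr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
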