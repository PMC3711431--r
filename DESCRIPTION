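Package: lacreg
Title: Deterministic and Stochastic Models of the Autoregulated lac Operon
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Models the Escherichia coli lactose utilization system with
    LacI autoregulation by transcriptional roadblock at the O3 operator.
    Provides a thermodynamic four-state promoter occupancy model with DNA
    looping, quasi-steady-state lactose/allolactose flux elimination,
    mean-field ordinary differential equation dynamics, and an exact
    Gillespie stochastic simulation engine for molecule counts. Includes
    experiment drivers reproducing dose-response curves and their dynamic
    range, stationary copy-number distributions, first-passage switch
    timing under lactose step protocols, and cumulative lactose
    metabolism, for the wild-type autoregulated circuit and fixed-low /
    fixed-high constitutive controls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
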