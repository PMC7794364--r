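Package: gbmflux
Title: Constraints-Based Metabolic Modeling of Drug-Sensitive and
    Drug-Resistant Glioblastoma Cell Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build, contextualize and compare constraints-based models of
    cancer cell-line metabolism. Provides a stoichiometric model container
    with COBRA-style JSON, TSV and SBML (Level 3 FBC) readers; flux balance
    analysis and flux variability analysis on a compiled bounded-variable
    simplex backend; artificial-centering hit-and-run sampling of the flux
    polytope; cell-line contextualization from biomass composition,
    measured exchange rates, ATP maintenance, oxygen-uptake capping and
    mutation-derived enzymopathy constraints; Gompertz growth-curve fitting
    and specific exchange-rate estimation from concentration time courses;
    and paired differential reports of flux spans and sampled flux
    distributions between two contextualized models.
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
    igraph,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    minpack.lm
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    pracma,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
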