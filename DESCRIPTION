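Package: porescale
Title: Scaling Analysis and Langevin Dynamics of Charged-Polymer
    Translocation Through a Nanopore
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying electric-field-driven translocation of
    polyelectrolytes through a nanopore in monovalent and divalent salt
    solutions. Implements the four-regime tension-propagation scaling
    theory (unbiased, weakly driven, strongly driven trumpet, strongly
    driven isoflux) in closed form, including regime boundaries, boundary
    slopes, inter-exponent relations, inversion of observed exponents and
    consistency inequalities; a coarse-grained bead-spring Langevin
    dynamics simulator with explicit ions, an in-pore driving field and a
    head-monomer no-return barrier; estimators for the scaling exponents
    (pairwise and least-squares log-log slopes, static size exponents,
    subdiffusion exponent of the translocation coordinate); and
    bidirectional conversion between simulation and experimental units.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
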