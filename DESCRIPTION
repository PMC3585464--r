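Package: pysub
Title: Analytical Steady States of Mass Action Models by py-Substitution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Derives exact analytical expressions for the non-trivial steady
    states of arbitrary mass action reaction networks by py-substitution: the
    species concentrations and rate constants are partitioned into a
    coefficient set P and a linear set Y so that every reaction velocity is
    homogeneous of degree one in Y, reducing the steady-state equation to a
    symbolic null-space computation over the fraction field of polynomials in
    the P symbols. Zero-order and superlinear velocities are linearized with
    pseudospecies whose constraints are resolved into solution branches.
    Includes a King-Altman solver (rooted spanning-tree patterns and
    principal minors) for the linear subclass with a symbolic equivalence
    check, and a numeric layer for perturbation simulation, dose-threshold
    binary search and normalized finite-difference sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
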