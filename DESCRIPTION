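Package: alchpath
Title: Metric-Based Lambda-Path Optimization for Alchemical Free Energy
    Calculations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for optimizing the lambda path and target distribution
    of alchemical free energy calculations. Implements Beutler-style
    soft-core pair coupling, an expanded-ensemble sampler with an adaptive
    weight-histogram bias, friction, diffusion and Fisher-Rao metric
    estimators from generalized-force time series, thermodynamic-length
    and variance functionals with optimal target distributions, shortest
    metric paths on two-dimensional lambda grids, and thermodynamic
    integration, BAR and MBAR free-energy estimators. Ships analytically
    tractable toy alchemical systems (harmonic oscillator, soft-core pair,
    two-dimensional micro-solvation, two-component lambda toy) for
    validation, together with GROMACS-style XVG and CSV input/output and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
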