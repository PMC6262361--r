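Package: flornet
Title: Data-Driven Modelling of the Flowering-Time Gene Regulatory Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary-differential-equation modelling of the core
    flowering-time gene network (TFL1a, TFL1c, FD, LFY, AP1 driven by the
    five chickpea FT homologs) with Hill-type regulation functions and
    data-driven regulator traces. Provides ensemble parameter estimation by
    differential evolution against a weighted residual sum of squares,
    small-sample Akaike (AICc) comparison of alternative FT-activation
    hypotheses, post-fit ensemble diagnostics (time-averaged regulation
    functions, Jacobian sensitivities, parameter clustering), descriptive
    expression statistics (Monte-Carlo integral expression, autocorrelation
    profiles, cross-gene correlation tables), and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
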