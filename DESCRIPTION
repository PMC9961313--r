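Package: fuzzyfdm
Title: Explicit Finite Differences for Fuzzy Time-Fractional
    Reaction-Diffusion Tumor Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Solves the one-dimensional time-fractional diffusion model of
    cancer tumor cell concentration with a space/time-dependent net killing
    rate under fuzzy (triangular) initial and boundary data.  The Caputo
    time derivative of order alpha in (0, 1] is discretized with an
    explicit L1-type finite-difference scheme; fuzzy quantities are handled
    in the double parametric (r, beta) form, so each (r, beta) sample
    reduces to a crisp run.  Includes the scheme's sufficient stability
    bounds with an empirical perturbation probe, an exact truncated-series
    oracle for the validated time-dependent killing-rate example, a naive
    direct-history reference stepper, and scripted experiments
    (error tables, fractional-order sweeps, grid refinement) returning
    tidy tibbles with ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
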