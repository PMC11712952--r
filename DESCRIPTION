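Package: dcslet
Title: LET and RBE-Weighted Dose Analysis for Dynamically Collimated
    Pencil Beam Scanning Proton Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational toolkit for studying how
    energy-specific collimation (nickel trimmer blades of a dynamic
    collimation system) changes the linear energy transfer (LET) and
    RBE-weighted dose of pencil beam scanning proton fields. Provides a
    condensed-history proton Monte Carlo with per-step track- and
    dose-averaged LET scoring, exit-plane spectral analysis with scatter
    fractions, analytic surrogate beamlets for fast composite-field
    planning, nonnegative spot-weight optimization, weighted composite
    LET recombination, and a phenomenological proton RBE model, together
    with dose/LET volume histogram and plan metric reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
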