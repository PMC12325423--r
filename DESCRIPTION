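Package: bileEEM
Title: PARAFAC Analysis of Fish Bile Fluorescence Excitation-Emission Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for characterising the fluorescence fingerprint of fish
    bile from excitation-emission matrix (EEM) dilution series: blank
    subtraction, Rayleigh/Raman scatter excision with gap interpolation,
    inner-filter-effect detection and thin-limit sample selection,
    non-negativity-constrained trilinear PARAFAC decomposition with
    core-consistency (CORCONDIA) and residual-sum-of-squares model selection,
    and model diagnostics (moving-window discrepancy maps, reduced major axis
    regression, score-dilution curves and equal-score concentration-ratio
    estimation). Includes a synthetic EEM study generator with known ground
    truth so the whole pipeline is testable without instrument data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
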