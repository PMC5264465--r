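Package: ilxpct
Title: Simulation and Quantification of In-Line X-Ray Phase-Contrast CT of
    Tumor Neovascularization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward simulation of propagation-based (in-line) X-ray
    phase-contrast imaging of soft-tissue specimens, parallel-beam filtered
    back projection reconstruction, and quantification of tumor
    neovascularization from the reconstructed volumes.  Includes a synthetic
    phantom generator for a liver lobe bearing a staged tumor xenograft with
    branching hepatic and tortuous tumor vessel trees, a Fresnel free-space
    propagator with Poisson noise and detector-gain (ring artifact)
    injection, edge-contrast and local-window contrast statistics,
    threshold-based vessel segmentation, vascular density and local-thickness
    vessel diameter estimation, and week-series trend reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    tiff,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
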