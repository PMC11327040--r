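Package: coroflow
Title: Reduced-Order Hemodynamics of Coronary Artery Stenosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale analysis of coronary artery stenosis hemodynamics.
    Builds parametric stenosed lumen geometries for the four main coronary
    arteries (LM, LAD, LCX, RCA) at any degree of diameter stenosis and
    eccentricity, couples them into a transient zero-dimensional (lumped
    parameter) blood-flow network with three-element Windkessel and
    intramyocardial-pressure coronary outlet circuits, integrates the network
    to a periodic solution with a second-order backward differentiation
    scheme, and quantifies fractional flow reserve (FFR), time-averaged wall
    shear stress (TAWSS), oscillatory shear index (OSI) and abnormal-area
    totals over a vessel-by-stenosis-degree-by-eccentricity sweep.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
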