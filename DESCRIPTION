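Package: nitrisphere
Title: Nitrification Source Partitioning, Rate Estimation and DNA-SIP
    Gradient Analysis for Estuarine Biofilms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies nitrification and associated N2O emission in
    estuarine biofilms (including the plastisphere) and seawater from
    tabular measurements. Implements N2O isotopocule calibration and
    site-preference (SP) computation, two-endmember partitioning of
    nitrification-derived N2O between hydroxylamine oxidation and
    nitrifier denitrification with Monte Carlo uncertainty propagation,
    15N-tracer ammonia- and nitrite-oxidation rate estimation normalized
    per microbial cell, and DNA stable-isotope-probing (SIP) CsCl
    buoyant-density gradient analysis with peak-shift labeling calls.
    Ships a seed-reproducible synthetic-data generator emulating the
    grouped incubation and gradient designs, and a pipeline layer that
    runs every stage from CSV inputs to machine-readable reports.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
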