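Package: fibrilmorph
Title: Amyloid Fibrillization Kinetics, Calorimetry and AFM Morphometry
Version: 0.1.0
Authors@R:
    person("fibrilmorph", "developers", email = "fibrilmorph@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of protein amyloid fibrillization
    experiments. Fits Boltzmann sigmoids to aggregation kinetics (ThT
    fluorescence or CD ellipticity) to extract lag times, half-times and
    apparent aggregation rate constants; analyzes differential scanning
    calorimetry thermograms with a two-state excess-heat-capacity model
    with independent calorimetric and van't Hoff enthalpies; and measures
    fibril ridge heights from AFM topographies by scanline flattening,
    ridge tracing, perpendicular cross-section Gaussian profiling and
    multi-peak height-histogram decomposition, interpreting the resulting
    peaks with a hierarchical protofilament assembly model. A synthetic
    data generator produces ground-truth-labelled inputs for all three
    pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
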