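Package: skmap
Title: 3D Quantification of Immunogold Particles on Reconstructed Dendrites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies immunogold particle distributions on 3D-reconstructed
    neuronal compartments from FIB/SEM label volumes. Classifies particles as
    plasma-membrane-bound or intracellular, measures geodesic nearest-neighbor
    distances along the membrane surface, tests spatial randomness against a
    Monte-Carlo null sharing the same membrane and particle number, calls
    particle clusters, profiles particle distances to synapse edges in
    fixed-width bins, and tabulates per-compartment densities. Includes a
    synthetic scene generator for spiny and smooth dendrites with ground-truth
    particles so the full pipeline is testable without microscopy data.
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
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
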