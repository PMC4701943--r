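Package: spinekit
Title: Morpho-Functional Analysis and Retrieval of Dendritic Spines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless toolkit for exploring the morpho-functional organisation of
    pyramidal-neuron dendritic spines. Computes per-spine morphometry (volume,
    surface area, length, maximum and neck mean diameters, three-way spine class)
    from triangle meshes by planar cross-sectioning along a graph-geodesic spine
    axis; estimates the membrane-potential peak each spine would generate under an
    alpha-function glutamatergic synapse with a passive lumped-cylinder
    compartmental model integrated by exponential Euler; and ranks or filters
    spines with a content-based retrieval engine over weighted, min-max normalised
    feature signatures. Ships a synthetic-data generator with analytic ground
    truth so the whole pipeline is testable without microscopy data, plus readers
    and writers for VRML 2.0 (Imaris export subset), OBJ and PLY meshes and CSV
    feature tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
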