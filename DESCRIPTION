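Package: evr
Title: Error-Vector Resultant Reconstruction of Bacterial Chromosome
    Structures from Hi-C Contact Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs 3D backbone models of circular (or linear)
    bacterial chromosomes from normalized 3C/Hi-C interaction-frequency
    matrices using iterative error-vector resultant optimization. Converts
    contact frequencies to expected spatial distances through a power law,
    drives a random initial conformation toward those distances with
    per-bin resultant vectors under an adjacent-bin distance band, and
    stops on a delta-F rule. Ships a synthetic benchmark suite (toroidal
    spiral standard structures, uniform matrix noise), scale-optimal
    Procrustes superposition with reflection handling, noise-robustness
    sweeps, marker-to-bin mapping with distance correlation, and xyz /
    PDB-like structure output.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
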