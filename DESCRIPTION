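Package: cystsim
Title: Hexagonal-Lattice Cellular Potts Simulation of Epithelial Cystogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based simulator of MDCK-style epithelial cystogenesis on a
    2D hexagonal lattice. Cells are multi-site cellular Potts (Glazier-Graner-
    Hogeweg) objects with area, perimeter and adhesion energies; they polarize,
    stabilize, divide with configurable axis orientation, die stochastically and
    create lumens at the site of prior division. Lumens expand under a growth
    law gated by tight-junction constraints and merge through tight-junction
    reorganization. The package includes the full morphometric measurement
    pipeline for simulated cyst cross-sections (cell number, cyst/lumen area,
    mean cell area, cellular-to-cyst ratio, lumen counts, single-layer
    single-lumen classification), batch replicate runners with preset
    intervention experiments, and the SM1/SM2/SSM1 similarity measures used to
    score simulated time courses against an in vitro reference series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
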