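Package: invadopotts
Title: Cellular Potts Simulation of Cancer Cell Invasion Through Fibrillar ECM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multiscale hybrid Graner-Glazier-Hogeweg (cellular Potts)
    model of cancer cell invasion. A 69-cell aggregate with adaptive,
    history-dependent polarity migrates through a fibrillar extracellular
    matrix lattice, coupled to a matrix-metalloproteinase (MMP) field that
    is secreted at cell-fibre contacts, diffuses, decays, and degrades
    fibres above a threshold. Includes ECM mesh generators (random and
    aligned fibre orientations), PIFF layout input/output, invasion metrics
    (total distance, net translocation, radius of gyration, percent ECM
    degradation, cluster statistics), and preset parameter sweeps over
    cell-cell adhesion, MMP secretion rate, fibre density and fibre
    alignment, with replicate management and summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
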