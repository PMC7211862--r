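Package: nmjmetrics
Title: Automated Morphometry of Neuromuscular Junctions from Two-Channel
    Confocal Images
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Batch-capable morphometric analysis of neuromuscular junctions
    (NMJs) imaged as two-channel confocal stacks (nerve-terminal stain and
    acetylcholine-receptor stain). Computes the 19 standard pre- and
    post-synaptic variables of standard NMJ morphometry workflows (areas,
    perimeters, skeleton branch statistics, Feret endplate diameter, AChR
    cluster counts with fill-holes enclosure handling, fragmentation,
    compactness, synaptic overlap) from maximum-intensity projections, with
    footprint-restricted cluster counting, aberrant-segmentation quality
    control, a seven-stage guided pipeline, a batch CLI, and a synthetic
    two-channel fixture generator with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    png,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
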