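Package: afmbridge
Title: Quantification of Protein-Mediated DNA Bridging in Fluid AFM Height Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end, ground-truthed pipeline for quantifying DNA-DNA
    junctions (bridges) in fluid atomic force microscopy height maps of short
    DNA fragments incubated with nucleoid-associated proteins. Provides a
    worm-like-chain scene simulator that renders synthetic height maps with
    known junction annotations, per-scanline polynomial background flattening,
    height-threshold particle segmentation, skeleton-graph molecule tracing
    with junction detection and intra/intermolecular classification,
    junction-height statistics, and density-stratified condition comparisons,
    together with small closed-form calculators for contour length and
    intracellular concentration estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
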