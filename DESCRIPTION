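Package: narscape
Title: Nucleoporin-Associated Chromatin Domain Calling and 3D FISH
    Radial Position Analysis
Version: 0.1.0
Authors@R:
    person("Maintainers", "narscape", email = "narscape@example.org",
           role = c("aut", "cre"))
Description: Detects nucleoporin-associated regions (NARs) from tiling
    ChIP signal by sliding-window positive-probe density, tests the
    enrichment of transcriptional-activity markers inside versus outside
    the called domains, and quantifies the sub-nuclear radial position of
    FISH-labelled loci in segmented 3D nuclei against simulated
    peripheral and interior reference distributions.  A synthetic-data
    module generates probe tracks, gene annotations and voxelized
    nucleus image stacks with the statistical structure the analysis
    assumes, so the whole pipeline is testable without array or
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    methods,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
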