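Package: hoxatlas
Title: Comparative Analysis of Insect Hox Gene Cluster Organisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects homeobox loci in genome assemblies by six-frame
    position-specific scoring, classifies them into the ten ancestral insect
    Hox paralogy classes (including zen-derived bcd, zen2 and Shx subtypes),
    reconstructs per-species cluster organisation (gene order, orientation,
    intergenic distances, core AbdB-Scr span, split points), calls structural
    events (splits, inversions, translocations, tandem duplications, losses)
    against the ancestral ten-gene order, and aggregates cross-species
    summaries (intergenic-distance distributions, copy-number matrices,
    cluster-size/genome-size correlations). A seeded synthetic-genome
    generator with planted truth tables makes every stage verifiable at desk
    scale without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo: Rcpp
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
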