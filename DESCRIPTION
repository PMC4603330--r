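Package: wgdsig
Title: Superblock Multiplicity Signatures of Ancient Whole-Genome Duplication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects the imprint of ancient polyploidy in a target genome by
    comparing it against a panel of reference genomes. Collinear homolog
    anchors are chained into syntenic blocks (a DAGchainer-style dynamic
    program, with import of precomputed block text), blocks whose footprints
    overlap in a reference genome are grouped into superblocks, and an
    exponential f(B) = a*exp(-c*B) is fitted to the tail of the empirical
    block-multiplicity distribution. The decay rate c, swept over reference
    genomes, block-validation thresholds and tail cutoffs, ranks genomes by
    inferred whole-genome-duplication history. A genome-evolution simulator
    (duplication, triplication, exponential fractionation, inversions and
    translocations) provides synthetic genome pairs with known truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
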