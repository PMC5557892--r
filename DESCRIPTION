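Package: chimeramap
Title: Mapping miRNA-Target Interactions from AGO-CLIP Chimeric Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies miRNA-target chimeras in Argonaute CLIP (CLEAR-CLIP)
    sequencing libraries and carries the interactions through a complete
    downstream characterization: PCR-duplicate collapsing on degenerate
    barcodes, interaction clustering with biological complexity, seed-site
    classification, constrained miRNA:target duplex prediction by a
    pair-scoring dynamic program, enumerative 7mer motif enrichment with a
    combined confidence statistic, AGO sequestration coefficients (ASC) with
    consensus k-means cooperativity, ceRNA region detection, and functional
    validation analyses (grouped CDF/KS fold-change comparisons, targetome
    overlap tests, chimera support of CLIP peaks with sigmoidal saturation).
    Includes a synthetic-data generator producing toy genomes, miRNomes,
    CLIP read libraries and expression tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
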