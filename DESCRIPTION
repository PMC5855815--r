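Package: aposenet
Title: Super-Enhancer Calling and Regulatory Network Integration for
    Unliganded Estrogen Receptor Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for identifying super-enhancers from
    H3K27ac ChIP-seq peaks and signal tracks (ROSE-style stitching, input
    subtracted ranking and tangent-slope cutoff), intersecting them with
    unliganded estrogen receptor alpha binding sites, associating
    super-enhancers with coding and lncRNA gene TSSs by center distance,
    classifying differential-expression tables and quantifying the
    down-regulation bias of receptor-bound genes, and building the
    promoter-enhancer chromatin interaction network from ChIA-PET anchor
    pairs. Includes a seeded synthetic-data generator that emulates the
    statistical structure of the real inputs so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
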