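Package: anchorasm
Title: Anchor-Guided Assembly of Ultra-High-Depth Synthetic Long Read Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Assembles the full-length sequence of a single captured molecule from
    an ultra-high-depth cloud of short reads flanked by known anchor sequences,
    as produced by synthetic long read (SLR) protocols such as LoopSeq Solo.
    Estimates the molecule length from the N50 kmer frequency, builds a weighted
    compacted de Bruijn graph, locates start/end anchor nodes by infix
    edit-distance search at escalating tolerance, and reports the
    length-constrained path maximizing the smallest node weight via a bounded
    priority-queue dynamic program. Ships a read-cloud simulator covering
    read-through, repeat-insertion and chimera artifact regimes, and a small
    alignment-based assembly evaluator (genome fraction, largest alignment
    ratio, mismatch and indel rates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
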