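Package: plasmidrift
Title: Neutral Dispersal and Shared-Segment Selection Analysis for Gut
    Plasmidomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to study how plasmids and their recombining segments
    disperse across human gut microbiome samples. Implements plasmid
    deduplication, coverage-based presence calling and depth filtering for
    abundance tables; circular-aware detection and greedy clustering of
    shared plasmid segments; fitting of the Sloan neutral community model
    with deviation-based detection of entities under selection;
    degree-preserving permutation null models over sample-sample
    segment-sharing networks with group, edge and segment significance
    tests; and hypergeometric enrichment and lifestyle statistics. A
    synthetic-data generator with known ground truth lets the whole
    pipeline be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
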