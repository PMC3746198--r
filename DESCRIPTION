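Package: nsmotif
Title: Joint Nanog/Sox2 ChIP-Seq Peak Consensus, Bipartite Motif
    Enrichment, Interactome Filtering and SELEX Simulation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls high-confidence joint Nanog/Sox2 binding events from
    summit-centred ChIP-seq peak sets across multiple datasets, scans them
    for the bipartite Nanog/Sox2 DNA recognition motif, quantifies motif
    over-representation with a hypergeometric tail test, links peaks to the
    nearest transcription start site, filters affinity-purification mass
    spectrometry hit tables into an interactome, and simulates SELEX motif
    selection with position weight matrix recovery. Ships a synthetic-data
    generator with known ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
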