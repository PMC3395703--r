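Package: pyrotagkit
Title: Simulation and Cross-Validation of Pyrotag Libraries and T-RFLP Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the reproducibility and semi-quantitative rigour of
    barcoded 16S rRNA gene amplicon (pyrotag) sequencing against terminal restriction
    fragment length polymorphism (T-RFLP) fingerprinting. Provides a ground-truth
    simulator for mock communities with spike-in template amendments and 454-style
    bidirectional barcoded reads; quality filtering (MID demultiplexing, degenerate
    primer checks, confidence trimming, length filters); greedy consensus assembly of
    forward and reverse reads into contigs; OTU linkage clustering and a bootstrap
    naive-Bayes k-mer taxonomy classifier; in-silico terminal restriction fragment
    prediction including pseudo-T-RFs from partial digestion; and the community
    statistics used to compare fingerprints and libraries (Shannon diversity, Sorensen
    similarity, Pareto-Lorenz functional organisation, replicate standard deviations,
    and spike-in recovery regression).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
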