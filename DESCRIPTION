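Package: poisedR
Title: Poised-Enhancer Classification, Conservation and Chromatin-Loop Topology
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rule-based classification of poised, active, primed and PoiAct
    enhancers from multi-mark ChIP-seq/ATAC-seq peak libraries; cross-species
    conservation scoring of enhancer sets through UCSC liftOver chain files
    with per-interval mapping ratios and threshold sweeps; association
    statistics linking enhancers to CpG islands and promoter chromatin states
    (Fisher enrichment, rank-sum comparisons, Polycomb-domain calling);
    chromatin-loop analytics on significance-annotated BEDPE loop lists
    (hierarchical anchor annotation, intra/inter-TAD classification,
    anchor-extended loop-set overlap); and binned contact-matrix pileups with
    coverage normalization, Knight-Ruiz balancing and a loopiness statistic.
    Includes a synthetic-data generator that plants enhancer classes,
    conservation fractions, loop categories and contact enrichments with a
    machine-readable truth manifest, plus a config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
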