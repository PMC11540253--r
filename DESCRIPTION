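Package: BarSeqFit
Title: Gene Fitness Analysis for Barcoded Transposon Mutant Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for random-barcode transposon sequencing (RB-TnSeq)
    competition experiments: simulation of barcoded mutant pools and their
    sequencing reads with known ground truth, barcode extraction and counting
    from BarSeq amplicon reads, mapping of barcodes to genomic insertion
    sites from TnSeq junction reads, gene-level fitness scoring from barcode
    abundance trajectories, mutant growth-rate estimation, silhouette-selected
    hierarchical clustering of fitness profiles with hypergeometric pathway
    enrichment, an operon-aware polar-effect protein-cost model, and
    growth-curve phenotyping (sliding-window maximum growth rate, biomass
    yield).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    withr,
    cluster,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
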