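Package: CLIPcompete
Title: Quantitative iCLIP Analysis of Competitive RNA-Binding Protein Occupancy
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for quantitative iCLIP analysis of
    protein-RNA binding and competition between RNA-binding proteins.
    Provides barcode-aware read demultiplexing and PCR-duplicate collapsing
    into single-nucleotide crosslink-event tracks, binding-site calling by
    within-gene randomization FDR, gene-normalized occupancy with
    median-of-ratios size factors and differential-binding categories,
    de novo exon filtering and Alu-exon classification with transcript
    disruption prediction, conditional thresholding across replicate
    knockdowns, RNA maps, pentamer enrichment and RBP co-binding profiles,
    consensus-coordinate mapping of repeat elements by pairwise alignment,
    and a cumulative-frequency U-tract selection statistic. A synthetic-data
    module generates toy genomes with intronic antisense Alu-like elements,
    planted binding-site competition and exon-inclusion ground truth for
    calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    Rsamtools,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Sequencing, Transcriptomics, AlternativeSplicing, PeakDetection,
    FunctionalGenomics
RoxygenNote: 7.3.3
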