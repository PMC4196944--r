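Package: poolsweep
Title: Selective Sweep Detection from Pooled Sequencing Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting signatures of domestication and artificial
    selection from Pool-seq data. Implements quality trimming of reads by a
    modified-Mott running-sum algorithm, SNP identification from per-pool
    nucleotide counts with a three-factor filtering scheme (minimum depth,
    maximum depth, minor allele read count) and its optimization grid,
    minor-allele-frequency spectra, common and strain-specific SNP
    classification, Fisher's exact allele-frequency differentiation between
    domestic and wild pools with FDR correction, and a sliding-window pooled
    heterozygosity (Hp) scan that calls and annotates putative selective
    sweep regions. A synthetic-data generator produces pooled counts, reads
    and annotation with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    BiocGenerics,
    tools,
    methods,
    stats,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Sequencing, SNP, PopulationGenetics, Coverage, QualityControl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
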