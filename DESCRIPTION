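Package: clumpscan
Title: Detection of Expressed Variant Allele Clumps on Cell Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and scores local enrichment ("clumps") of expressed variant
    alleles on low-dimensional embeddings of single-cell and bulk RNA-seq samples.
    Includes a pileup-based SNV/indel caller with coverage, allele-frequency and
    strand-bias filters, coding-impact annotation and population-frequency
    filtering, per-cell allele count matrices, binary copy-number matrices at
    chromosome-arm and minimal-segment resolution, multiscale Gaussian smoothing
    of allele frequencies with local-maximum clump candidate selection,
    read-depth-aware permutation z-scores, read-level binomial and cell-level
    Fisher enrichment tests, effective clump radii, a clump simulator for
    benchmarking detection sensitivity, and plotting of clumps on embeddings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
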