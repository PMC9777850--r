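Package: yakcnv
Title: Read-Depth CNV Calling, CNVR Construction and Two-Group Comparison
    for Resequenced Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested workflow for copy-number-variation analysis of two
    closely related resequenced populations: per-sample read-depth CNV
    detection from binned depth profiles (GC correction, median
    normalisation, threshold-run segmentation with a >0.5 kb retention
    filter), cross-sample merging of calls into CNV regions by single-linkage
    1-bp overlap with a >=4-sample frequency filter, gene annotation against
    a GFF3 model with intronic-only removal, two-group differential gene
    sets and summary tables, hypergeometric term enrichment with
    Benjamini-Hochberg FDR, and qPCR delta-delta-Ct copy-number validation.
    Includes a synthetic-cohort generator (genomes with a GC landscape,
    planted deletions and duplications, negative-binomial depth noise,
    qPCR Ct tables) so the whole pipeline is exercisable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    BiocGenerics,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
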