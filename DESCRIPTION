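Package: inbredvar
Title: Nucleotide and Structural Variation Analysis for Inbred Resequencing Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for whole-genome resequencing panels of inbred lines:
    site-level nucleotide-variant filtering and functional classification,
    genotype concordance between platforms, a leave-one-out untyped-locus
    imputation-accuracy protocol, pairwise linkage disequilibrium with
    window-based tag-SNP pruning and saturation curves, multi-caller
    structural-variant consensus construction by reciprocal overlap and
    breakpoint offset, SV gene-impact classification, and detection of
    clustered residual heterozygosity caused by collapsed duplications.
    Includes a synthetic-cohort generator with known ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
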