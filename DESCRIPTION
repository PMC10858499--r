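Package: rebivalent
Title: Sequential ChIP (reChIP) Analysis of Bivalent Chromatin
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing sequential chromatin immunoprecipitation
    (ChIP-reChIP) experiments that map bivalent chromatin, the co-occurrence
    of H3K4me3 and H3K27me3 on the same nucleosome. Provides a Poisson
    island peak caller for diffuse histone marks, reciprocal-reChIP bivalent
    region calling with four-class confidence stratification, hierarchical
    promoter classification, quality-control metrics (FRiP, log2 CPM/bp,
    profile matrices, downsampling curves), TMM-normalised negative-binomial
    differential bivalency testing, GC/CpG sequence metrics against matched
    random regions, and a generative simulator of one- and two-round
    immunoprecipitation that distinguishes bone-fide bivalency from allelic
    and cellular heterogeneity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
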