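Package: spliceMeth
Title: Analysis of N6-Methyladenosine at 3' Splice Sites
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study N6-methyladenosine (m6A) deposited by the
    METTL16/METT-10 family of methyltransferases on the adenosine of 3'
    splice sites (the acceptor AG), where the mark blocks U2AF35 binding
    and splicing. The package enumerates annotated 3' splice sites from a
    genome and transcript annotation, screens them for the methylation
    consensus motif inside a foldable stem-loop (deterministic base-pair
    maximisation folding with a dot-bracket similarity score), quantifies
    protein-coding, alternatively spliced and intron-retained isoform
    abundances from splice-junction counts and per-base coverage,
    tests per-gene loss or gain of m6A-IP/input enrichment between
    genotypes with a negative-binomial interaction likelihood-ratio test,
    computes relative splice-site usage normalised to gene expression,
    builds binned metagene coverage profiles, and generates fully
    seeded synthetic datasets with ground-truth manifests for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    MASS,
    DESeq2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: RNASeq, Epitranscriptomics, AlternativeSplicing,
    DifferentialMethylation, Coverage, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
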