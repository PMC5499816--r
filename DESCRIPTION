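Package: catac
Title: Probabilistic Modelling and Rhythm Analysis of the CATAC Promoter Element
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the 29-bp CATAC (Clock-Associated
    Transcriptional Activation Cassette) cis-regulatory element in Drosophila.
    Builds and refines position weight matrices from aligned motif sites
    (ZOOPS-style expectation maximization), scans promoter sequences by
    log-odds bit score with BED output, and tests gene-set enrichment of
    motif occurrences by the hypergeometric tail. Represents multimerized
    4xCATAC enhancer constructs assembled from synthetic oligonucleotide
    duplexes, scores their core and E-box regions against IUPAC consensus
    patterns, and applies the transversion mutation operator used for mutant
    constructs. Analyses in vivo bioluminescence recordings by iterative
    FFT-seeded nonlinear least-squares multicomponent cosine fitting with
    relative-amplitude-error based rhythmicity classification and group
    statistics, and qRT-PCR time courses by the comparative Ct method with
    Kruskal-Wallis rhythm testing. A synthetic-data module generates
    luciferase traces, promoter sequences with planted motif instances, and
    Ct tables with stored ground truth for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    minpack.lm,
    rtracklayer,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
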