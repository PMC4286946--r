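Package: pirnapipe
Title: Small Non-Coding RNA Profiling and piRNA Cluster Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for profiling small non-coding RNA libraries
    from germline and somatic cells: FASTQ read cleaning (adapter trimming,
    mean-quality and length filters), collapsing of reads into unique tags,
    seed-and-extend genome mapping under an identity/coverage contract,
    hierarchical annotation of tags against repeat, genic and structural
    ncRNA features, RPKM-based cross-sample upregulation tables, and
    probabilistic piRNA cluster prediction from locus density, strand bias,
    the 1U/10A ping-pong signature and the 26-32 nt length signature. A
    synthetic genome and library simulator with full truth labels supports
    validation and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    jsonlite,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
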