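Package: stamper
Title: Simulation and Analysis of RNA Base-Editor Profiling Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing RNA base-editor
    (rBE) profiling experiments of the STAMP/TRIBE family, in which a C-to-U
    or A-to-I deaminase fused to an RNA-binding protein deposits edits near
    its binding sites. Provides a ground-truth simulator for tethering
    reporters (MS2/PP7 stem-loop constructs) and toy transcriptomes; edit-site
    calling from read pileups with a Beta-posterior confidence score;
    Poisson-based edit-cluster detection with Benjamini-Hochberg control,
    bin merging, replicate intersection and free-editor background
    subtraction; flanking-base sequence-context characterisation with PCA; a
    compact convolutional sequence classifier for enzyme attribution;
    edits-per-read (EPR) translation profiling with treated-versus-control
    contrasts; and permutation tests for interval-set overlap enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    withr,
    generics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    methods,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
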