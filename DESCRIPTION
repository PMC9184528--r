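Package: paracn
Title: Aggregate and Paralog-Specific Copy Number from Short-Read Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates aggregate and paralog-specific copy number of low-copy
    repeats (segmental duplications) from short-read whole-genome sequencing.
    Builds a homology table of pairwise duplications with paralogous sequence
    variants (PSVs) extracted from the stored alignments, fits GC-stratified
    negative binomial background depth models per sample, pools reads across
    repeat copies onto a primary copy, segments aggregate copy number with a
    multi-sample hidden Markov model, jointly estimates paralog-specific copy
    number and PSV reference-allele frequencies by expectation-maximization,
    genotypes single samples from frozen model parameters, and checks
    Mendelian consistency of calls in parent-offspring trios. A bundled
    simulator generates toy genomes, depth matrices, PSV allele counts and
    trios so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    MASS
Config/testthat/edition: 3
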