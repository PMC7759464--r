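Package: diverscan
Title: Classifying Shared and Divergent Selective Sweeps Between
    Sympatric Population Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pairwise selection-scan pipeline for phased population
    genomic data. Simulates labelled two-population loci (neutral, shared
    sweep, divergent sweep) under a colonization-split demographic history
    with a rescaled forward-in-time Wright-Fisher engine, summarises loci
    as normalized matrices of windowed population-genetic statistics
    (pi, Tajima's D, Fay and Wu's H, Garud's H1/H12/H2-H1, 1-HAF, Hudson's
    FST, DXY, Gmin, SS-H12), trains a small convolutional classifier on the
    simulated feature matrices, and applies it along empirical chromosomes.
    Also provides windowed Hudson-FST genome scans with loess smoothing,
    outgroup-polarized two-dimensional site-frequency spectra, drift-null
    genome simulations with an Ne-swap experiment, and a synthetic-fixture
    generator producing phased VCF cohorts with known planted sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    IRanges,
    Biostrings,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
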