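Package: extremesig
Title: Alignment-Free Genomic Signatures for Extremophile Genome Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for alignment-free comparison of microbial genomes via
    k-mer frequency genomic signatures. Builds composite genome proxies by
    pseudo-concatenating randomly sampled non-overlapping sub-fragments,
    computes canonical k-mer vectors and Frequency Chaos Game Representation
    (FCGR) matrices, and runs supervised classification harnesses with both
    standard stratified and genus-grouped (bias-mitigation) cross-validation.
    A multilayered unsupervised pipeline detects maximally divergent
    bacterium-archaeon pairs with similar genomic signatures: consensus
    clustering across reducer-clusterer combinations, FCGR image-distance
    filtering against intra-genus derived thresholds, environment-label
    hypothesis testing, 3-mer frequency profile scoring (Shapley-attributed
    environment-relevant 3-mers, Spearman correlation, combined scores), and
    geographic co-occurrence cross-referencing. Includes a seeded synthetic
    genome generator with planted taxonomic and environmental structure so
    the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    png,
    randomForest,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
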