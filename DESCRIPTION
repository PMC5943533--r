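Package: cyanomcp
Title: Myocyanophage Major Capsid Protein Amplicon Diversity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for short (~145 bp) degenerate-primer
    amplicons of the T4-like cyanophage g23 major capsid protein gene.
    Provides IUPAC/inosine degenerate-primer matching and in-silico PCR,
    barcode demultiplexing and primer trimming, quality filtering, a
    frame-aware codon-length and stop-codon filter with length-class
    bookkeeping, greedy centroid OTU clustering at multiple identity
    thresholds, alpha diversity (exact and Monte Carlo rarefaction, Good's
    coverage), distance trees, weighted and unweighted UniFrac, principal
    coordinates analysis, and jackknife-supported UPGMA sample clustering.
    A seedable synthetic amplicon generator with full ground truth makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    phyloseq,
    vegan,
    withr,
    optparse
LinkingTo:
    Rcpp
Config/testthat/edition: 3
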