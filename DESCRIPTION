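Package: splicelib
Title: Design, Simulation and Quantification of Massively Parallel Synthetic Intron Splicing Assays in Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for massively parallel splicing reporter assays in budding
    yeast. Generates combinatorial synthetic intron oligo libraries (splice-site
    catalogs, barcode codes with guaranteed edit distance, start-codon
    scrubbing, natural-intron and two-intron designs, structure mutants),
    simulates merged targeted-amplicon reads with known ground-truth isoform
    mixtures, quantifies splicing efficiency per variant by junction-based
    Smith-Waterman classification including cryptic alternative 3' splice
    sites and five-isoform two-intron calls, computes 3' splice-site motif
    avoidance resampling statistics on annotated genomes, and fits a
    gradient-boosting model of splicing efficiency with Shapley feature
    attribution.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
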