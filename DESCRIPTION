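Package: metajoint
Title: Joint Analysis of Multiple Metagenomic Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint multi-sample analysis of shotgun metagenomic sequencing
    data. Fits a shared-component mixture of multinomials (probabilistic
    latent semantic analysis) to per-sample canonical k-mer counts by two
    expectation-maximization variants, performs metagenome-wide k-mer
    association tests with component-based stratification correction, and
    implements MultiBin, a coverage-based read-binning algorithm that
    clusters reads across multiple samples simultaneously using tag reads
    selected from a read-overlap graph. Includes synthetic-community and
    mixture simulators with known truth labels for method evaluation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
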