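Package: lcimpute
Title: Benchmarking Missing-Value Imputation for LC-MS Metabolomics Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the missingness mechanisms that affect untargeted
    LC-MS metabolomics feature tables (missing completely at random, missing
    at random driven by a correlated feature, left-truncated missing not at
    random, and their sequential combinations), imputes the resulting
    incomplete matrices with nine methods spanning single-value replacement
    (zero, mean, minimum, half-minimum), local-structure methods (feature-wise
    k-nearest neighbours and iterative random-forest imputation), and
    global-structure methods (iterative low-rank SVD, probabilistic PCA and
    Bayesian PCA fitted by EM), and scores every method by the normalized
    root mean squared error over repeated seeded permutations. Includes a
    generator for complete, positive, right-skewed intensity matrices with
    low-rank inter-feature correlation, CSV input/output and a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
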