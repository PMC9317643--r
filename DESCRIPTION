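Package: pairedimpute
Title: Imputation Strategies for Paired-Biospecimen Metabolomics Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for studying how missing-value imputation
    distorts the intra-subject correlation structure of metabolomics studies
    that assay two biospecimens (e.g. plasma and serum) from the same
    subjects. Generates paired abundance matrices with controlled
    between-biospecimen correlation, induces detection-limit-weighted
    (left-censored plus random) missingness at exact overall rates, imputes
    under separate or combined (stacked) matrix strategies with five methods
    (half-minimum, k-nearest-neighbour, iterative random forest,
    bootstrap-EM multivariate normal, and quantile-regression imputation of
    left-censored data), and quantifies the bias in between-biospecimen
    correlation estimates together with the sensitivity, specificity and
    accuracy of two-group MANOVA significance calls relative to the complete
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ranger,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
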