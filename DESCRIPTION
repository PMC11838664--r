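Package: gtaccc
Title: Genomic Taxometric Analysis of Continuous and Case-Control Data
Version: 0.1.0
Authors@R: person("gtaccc", "authors", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tests genetic continuity versus differentiation across the
    severity spectrum of a continuous trait. A continuous score is binarized
    at multiple severity cut points, each binarization is analysed by GWAS,
    and the resulting summary statistics are entered into multivariate LD
    score regression to estimate a genetic covariance/correlation matrix
    together with the joint block-jackknife sampling covariance of its
    elements. Severity trends in genetic correlations are then tested by
    generalized least squares, and low/mid/high severity-factor structural
    equation models are fitted by diagonally weighted least squares with
    sandwich standard errors. A simulator with a planted severity-gradient
    genetic architecture makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
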