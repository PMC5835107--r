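Package: sobolclimb
Title: Expression Landscape Ruggedness and High-Throughput Batch Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating the optimization of multi-gene expression
    systems. Builds sum-of-Gaussians fitness landscapes over bounded
    expression spaces, quantifies their ruggedness by binned landscape
    autocorrelation analysis with a least-squares fit of the NK-model
    reference curve, and runs three high-throughput low-iteration batch
    optimizers (Sobol hill climbing, Sobol projection, and a simplified
    covariance-matrix-adaptation variant) across grids of sampling-radius
    and parent-fraction parameters, scoring performance and reliability
    over replicate runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
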