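Package: grntopo
Title: Topological and Statistical Analysis of Gene Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds directed transcription-factor to target-gene networks from
    protein-DNA interaction (PDI) tables or ChIP peak locations, and tests
    their scale-free out-degree connectivity with a discrete power-law
    toolkit: maximum-likelihood exponent estimation with data-driven
    minimum-degree selection, semiparametric Kolmogorov-Smirnov bootstrap
    goodness-of-fit, Vuong non-nested model selection against Poisson and
    exponential alternatives, and two-sample distribution comparisons.
    Quantifies inequality of TF-target binding with Lorenz curves and Gini
    coefficients, and provides Monte-Carlo machinery to infer properties of
    complete (unobserved) networks: prediction intervals for the scaling
    exponent, estimation of total interaction counts with Z-test validation,
    edge-sampled subnetwork analysis with knee-point detection, and
    generation of in-silico regulatory networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    igraph,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
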