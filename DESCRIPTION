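Package: spikesw
Title: Functional Connectivity and Small-World-ness from Multi-Neuron Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs directed functional connectivity from multi-neuron
    spike trains with an L1-penalised Laguerre-basis generalized linear model,
    validates fitted models by time-rescaling and ROC prediction accuracy, and
    quantifies the small-world character of the resulting graph with the S and
    omega metrics. Includes a three-dimensional distance-dependent network
    simulator with virtual multi-electrode subsampling, a two-term exponential
    model of the subsampling bias in the omega metric together with the
    corresponding adjustment of sampled small-world-ness, and minimum driver
    node computation for structural controllability via maximum bipartite
    matching.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    minpack.lm,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
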