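Package: kinergm
Title: Dyad-Independent Exponential Random Graph Models for IBD Kinship Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds networks of biological kinship by thresholding pairwise
    identity-by-descent (IBD) sharing, and models the drivers of their topology
    with dyad-independent exponential-family random graph models (Bernoulli
    dyad regression with logistic link). Provides homophily and mixing terms
    (nodematch, differential nodematch, nodemix), maximum-likelihood fitting
    with Wald inference and fold-change effect sizes, model selection by
    information criteria (BIC, AIC, AICc) or backward elimination, simulation
    of networks from any dyad-independent model, confusion-matrix and
    empirical-power experiments, minimum-detectable-effect analysis,
    cutoff-sensitivity analysis, and Louvain community detection with
    centrality summaries on the resulting relatedness graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse,
    MASS,
    knitr
Config/testthat/edition: 3
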