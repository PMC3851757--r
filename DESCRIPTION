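Package: ephysqc
Title: Automated Quality Assessment of Intracellular Electrophysiological Recordings
Version: 0.1.0
Authors@R:
    person("ephysqc", "developers", email = "ephysqc@example.org", role = c("aut", "cre"))
Description: Rule-based spike detection and a 16-feature encoding of
    intracellular (sharp-electrode style) voltage traces, together with a
    linear support vector machine classifier for rating recording quality as
    good, intermediate or bad. Feature relevance is established by an
    exhaustive wrapper search over all feature subsets with repeated k-fold
    cross-validation; voting ensembles over the best subsets and a two-stage
    leave-one-out procedure give selection-bias-free performance estimates.
    A synthetic trace generator with ground truth makes the full pipeline
    testable without access to laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
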