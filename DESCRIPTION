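Package: attractorscreen
Title: Attractor-Landscape Analysis and In Silico Perturbation Screening
    for Logical Disease Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Synchronous Boolean network simulation for molecular regulatory
    models of disease, with attractor-landscape and basin-of-attraction
    analysis (exhaustive or sampled over random initial states),
    basin-weighted node activities, a weighted phenotype score over
    pathological output nodes, risk-factor-conditioned single- and
    double-node perturbation screens, mapping of ranked targets onto an
    approved-drug library with property-based exclusion filters (blood-brain
    barrier penetrability, carcinogenicity), and graded oxidative-stress
    dose-response profiling. Ships a hand-verifiable Alzheimer's-disease
    pathway fixture and Kauffman-style random network generators so the
    whole pipeline is testable without external model files. Rule files use
    a BoolNet-dialect plain-text format with a YAML annotation sidecar for
    node roles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
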