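Package: nichepart
Title: Strain-Level Niche Partitioning Analysis for Amplicon Time Series
Version: 0.1.0
Authors@R: person("Lake Microbiome Analytics", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to dissect niche partitioning among closely related
    bacterial strains sampled repeatedly over time. Provides a simplified
    minimum entropy decomposition of aligned amplicon reads into exact
    sequence variants, detection of conditionally rare taxa via the
    bimodality coefficient, centered log-ratio transforms with
    multiplicative zero replacement, SparCC-style compositional
    correlation inference with bootstrap significance, latent variable
    models of taxon-environment responses, and regressions of niche
    similarity against pairwise genetic (p-) distance. A synthetic-study
    generator with distance-structured niche coefficients makes every
    stage testable without external data, and a pipeline driver runs the
    full analysis from one configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
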