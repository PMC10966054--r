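Package: statemapper
Title: Mapper Shape Graphs and Optimal-Transport Topology of Multi-State
    Brain Dynamics
Version: 0.1.0
Authors@R:
    person("statemapper", "developers", email = "statemapper@example.org",
           role = c("aut", "cre"))
Description: Constructs Mapper shape graphs from labeled time-by-feature
    recordings (e.g. concatenated multi-state fMRI scans), computes
    topological descriptors of the resulting brain-state landscape --
    exact 1-Wasserstein optimal-transport distances between per-state node
    distributions with graph-geodesic ground cost, label-weighted closeness
    and degree centralities, and label diameters -- and runs the matching
    statistical battery (mixed two-way ANOVA, Welch and paired t tests,
    Kendall and Pearson correlation matrices with an effective-number-of-tests
    correction, Benjamini-Yekutieli FDR, random-intercept mixed linear models,
    and a median-split test). Ships a seeded synthetic cohort generator that
    emulates a six-state, two-group pre/post design so the whole pipeline is
    testable end to end without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    nlme,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
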