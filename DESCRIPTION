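Package: scnet
Title: Structural Covariance Network Analysis of Regional Brain Volumes
Version: 0.1.0
Authors@R:
    person("scnet", "developers", email = "scnet@example.org", role = c("aut", "cre"))
Description: Builds group-level structural covariance networks from tables of
    per-subject regional brain volumes (e.g. FreeSurfer cortical, subcortical
    and thalamic-nucleus volumes), computes weighted graph-theory summary
    measures (global and local efficiency, mean clustering coefficient,
    characteristic path length, average strength, average degree,
    assortativity), and compares groups with label-permutation tests and
    Benjamini-Hochberg false discovery rate correction. Includes a synthetic
    cohort generator with known covariate effects and prescribed inter-regional
    correlation structure, a configurable end-to-end pipeline, and a
    command-line interface with a bundled demonstration run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
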