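Package: regpath
Title: Regulatory Path Discovery in Heterogeneous miRNA-Gene-TF Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering candidate regulatory paths between a
    source molecule and a target molecule in an integrated
    miRNA-gene-transcription-factor network. Combines consensus
    miRNA-target voting across prediction tools (keep targets called by at
    least k tools, then take the per-miRNA union), integration of
    protein-protein interaction, TF-to-miRNA and miRNA-to-target edge
    layers into one typed directed multigraph, and bounded depth-first
    enumeration of reachable nodes, simple source-to-target paths and the
    hierarchical search tree. Also provides the accompanying quantitative
    statistics: delta-delta-Ct relative expression from qPCR tables,
    percent suppression/induction conversion, calcification-assay
    normalization, cohort descriptive summaries, and pooled two-sample
    t-tests from raw values or printed summary statistics. A synthetic-data
    module generates interaction databases with planted paths, qPCR tables
    with planted fold changes, and two-group serum cohorts, so the full
    pipeline is testable without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
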