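Package: pleiosim
Title: Coevolution of Immune Signaling Networks and Manipulative Parasites
    under Pleiotropic Constraint
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Agent-based simulator of host immune signaling networks
    coevolving with signal-manipulating parasites. Hosts are signed,
    directed protein-interaction networks (one detector, one effector,
    evolving signaling proteins) whose within-host dynamics follow a
    discrete-time active/inactive-fraction update; parasites target one
    signaling protein. Supports four pleiotropic constraints on a focal
    signaling protein (fixed-random, fixed-up, fixed-down, slow),
    fitness-weighted death and reproduction, competitive simulations
    between pleiotropic and non-pleiotropic populations, and the
    accompanying analysis toolkit: inducibility of the immune response,
    boundary-corrected kernel density summaries and their correlation,
    signaling-protein knockout robustness, network connectivity and
    vertex-disjoint detector-to-effector paths, modal-network extraction,
    and lineage-split detection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
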