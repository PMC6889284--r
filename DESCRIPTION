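Package: respnet
Title: Agreement Networks and Conceptual Profiles from Multiple-Choice Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyzes multiple-choice assessment responses (e.g., the Force
    Concept Inventory) as a student agreement network. Projects the bipartite
    students-by-responses incidence onto a weighted student graph, extracts its
    statistical backbone by locally adaptive nonparametric edge significance,
    partitions students into groups by minimizing the two-level map equation,
    screens groups for head-motion confounds, and profiles each group's
    incorrect answers against a catalog of conceptual (misconception) modules.
    Includes a synthetic-data generator that plants known group structure so
    the whole pipeline is verifiable by recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mclust,
    optparse
Config/testthat/edition: 3
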