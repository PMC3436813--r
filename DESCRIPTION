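Package: dtli
Title: Gene-Tree/Species-Tree Reconciliation with Duplication, Transfer,
    Loss and Incomplete Lineage Sorting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconciles rooted binary gene trees with rooted, possibly
    non-binary species trees under a duplication-transfer-loss parsimony
    model extended with incomplete lineage sorting at species polytomies
    (the DTLI model).  A two-pass dynamic program enumerates every
    minimum-cost event history, each history is screened for temporal
    feasibility of its horizontal transfers via an acyclicity test on a
    constraint (timing) graph, and complete annotated histories are
    reported together with per-lineage event tallies.  Batch utilities
    aggregate event counts across gene-tree collections and model
    variants, root gene trees by event parsimony, and flag transfer
    highways between species pairs.  A simulator plants known
    duplication/transfer/loss/ILS histories on a species tree and a
    brute-force enumerator provides an independent oracle for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    data.table,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
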