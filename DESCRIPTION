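Package: bnscreen
Title: Static Screening for Dynamically Relevant Nodes in Boolean Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies nodes that drive the dynamics of Boolean gene-regulatory
    networks using only static, interaction-graph measures. Computes dynamic
    impact by exhaustive or sampled attractor analysis under knock-out and
    over-expression perturbations, vertex betweenness and determinative power
    (truth-table mutual information) from the interaction graph, selects the
    top-fraction intersection of the two static measures, and classifies
    selected nodes into hubs, gatekeepers (positive mismatches) and negative
    mismatches. Includes simple-path mutual-information profiling towards hubs,
    canalysing-variable detection, signed feed-forward-loop and bifan motif
    counting, and minimum feedback vertex sets. Reads and writes logical models
    in the plain-text "targets, factors" format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
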