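#' Mutual information carried by one regulatory edge
#'
#' Mutual information between the state of gene `from` and the output of gene
#' `to`'s transition function, under independent Bernoulli(`bias`) node
#' states. Writing `p1` for the probability that the function outputs 1, the
#' value is
#' `h(p1) - P(X_from = 0) h(p1 | X_from = 0) - P(X_from = 1) h(p1 | X_from = 1)`
#' with `h` the binary entropy (`h(0) = h(1) = 0` by continuity). Probabilities
#' are evaluated over the input space of the target's function only; a gene
#' that is not an input (or not an essential one) carries zero information.
#'
#' @param net A [boolean_network()].
#' @param from Candidate regulator gene.
#' @param to Target gene (must have a function in `net`).
#' @param bias Marginal probability of a node being 1 (default 0.5).
#' @return A number in \[0, 1\].
#' @examples
#' net <- parse_boolnet("targets, factors\nA, B & C\nB, A\nC, A")
#' edge_mutual_information(net, "B", "A")  # h(0.25) - 0.5
#' @export
edge_mutual_information <- function(net, from, to, bias = 0.5) {
  f <- net$functions[[to]]
  if (is.null(f)) stop("unknown gene: ", to)
  k <- length(f$inputs)
  pos <- match(from, f$inputs)
  if (is.na(pos) || k == 0) return(0)

  rows <- 0:(2^k - 1)
  bits <- int_to_states(rows, k)
  prob <- apply(bits, 1, function(b) prod(ifelse(b == 1, bias, 1 - bias)))
  p1 <- sum(prob[f$table == 1L])

  gbit <- bits[, pos]
  p_g <- c(`0` = 1 - bias, `1` = bias)
  cond <- vapply(c(0L, 1L), function(b) {
    sel <- gbit == b
    if (p_g[b + 1L] == 0) return(0)
    sum(prob[sel & f$table == 1L]) / p_g[b + 1L]
  }, numeric(1))

  mi <- binary_entropy(p1) - sum(p_g * vapply(cond, binary_entropy, numeric(1)))
  max(mi, 0)  # guard against floating-point dust below zero
}

binary_entropy <- function(p) {
  if (p <= 0 || p >= 1) return(0)
  -p * log2(p) - (1 - p) * log2(1 - p)
}

#' Determinative power of every gene
#'
#' The determinative power of a gene is the sum, over all genes of the
#' network, of the mutual information between the gene's state and the
#' target's function output ([edge_mutual_information()]). Only the gene's
#' out-neighbours contribute, so the value lies between 0 and the gene's
#' out-degree.
#'
#' @inheritParams edge_mutual_information
#' @return Named numeric vector in gene order.
#' @export
determinative_power <- function(net, bias = 0.5) {
  dp <- stats::setNames(numeric(length(net$genes)), net$genes)
  for (to in net$genes) {
    for (from in net$functions[[to]]$inputs) {
      dp[from] <- dp[from] + edge_mutual_information(net, from, to, bias = bias)
    }
  }
  dp
}

#' Static score table for a network
#'
#' Computes every static, interaction-graph based measure used by the
#' screening in one pass: vertex betweenness, determinative power, degrees,
#' standard and robust connectivity z-scores, and the hub flag (z >= 2.5).
#'
#' @param net A [boolean_network()].
#' @param bias State bias for the determinative power (default 0.5).
#' @param graph_mode Edge definition for the interaction graph
#'   (`"essential"` or `"syntactic"`).
#' @param hub_cutoff Connectivity z-score at or above which a node is a hub.
#' @return Tibble with one row per gene: `gene`, `vb`, `dp`, `in_degree`,
#'   `out_degree`, `degree`, `z`, `z_robust`, `hub`. The interaction graph is
#'   kept in attribute `"graph"`.
#' @examples
#' net <- generate_random_network(8, k = 2, seed = 1)
#' static_scores(net)
#' @export
static_scores <- function(net, bias = 0.5,
                          graph_mode = c("essential", "syntactic"),
                          hub_cutoff = 2.5) {
  graph_mode <- match.arg(graph_mode)
  graph <- build_interaction_graph(net, mode = graph_mode)
  vb <- vertex_betweenness(graph)
  dp <- determinative_power(net, bias = bias)
  z <- connectivity_zscore(graph)
  zr <- connectivity_zscore(graph, robust = TRUE)
  out <- tibble::tibble(
    gene = net$genes,
    vb = unname(vb[net$genes]),
    dp = unname(dp[net$genes]),
    in_degree = unname(igraph::degree(graph, mode = "in", loops = TRUE)[net$genes]),
    out_degree = unname(igraph::degree(graph, mode = "out", loops = TRUE)[net$genes]),
    z = unname(z[net$genes]),
    z_robust = unname(zr[net$genes]),
  )
  out$degree <- out$in_degree + out$out_degree
  out$hub <- out$z >= hub_cutoff
  out <- out[, c("gene", "vb", "dp", "in_degree", "out_degree", "degree",
                 "z", "z_robust", "hub")]
  attr(out, "graph") <- graph
  attr(out, "degenerate_z") <- isTRUE(attr(z, "degenerate"))
  out
}
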