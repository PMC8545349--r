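#' Essential inputs of a Boolean function
#'
#' An input is essential when the function's output depends on it for at least
#' one assignment of the remaining inputs. Published logical models sometimes
#' list regulators that never change the output; those are dropped here so
#' that graph measures and edge mutual information stay consistent (the mutual
#' information carried by an inert edge is zero).
#'
#' @param f A [bn_function()].
#' @return Character vector of essential input names (possibly empty), in the
#'   function's input order.
#' @examples
#' essential_inputs(bn_function(c("A", "B"), c(0, 0, 1, 1)))  # only A
#' @export
essential_inputs <- function(f) {
  k <- length(f$inputs)
  if (k == 0) return(character(0))
  rows <- 0:(2^k - 1)
  keep <- vapply(seq_len(k), function(i) {
    pos <- k - i  # bit position of input i (first input = MSB)
    lo <- rows[bit_at(rows, pos) == 0L]
    any(f$table[lo + 1L] != f$table[bitwOr(lo, bitwShiftL(1L, pos)) + 1L])
  }, logical(1))
  f$inputs[keep]
}

#' Build the interaction graph of a Boolean network
#'
#' Directed graph with one node per gene and an edge `g -> g'` whenever `g`
#' regulates `g'`. By default only essential dependencies (inputs the function
#' actually responds to) produce edges; `mode = "syntactic"` keeps every
#' regulator listed in the expressions, for parity with tools that read the
#' model text verbatim. Self-loops are retained.
#'
#' @param net A [boolean_network()].
#' @param mode `"essential"` (default) or `"syntactic"`.
#' @return An [igraph::igraph] directed graph whose vertex order matches the
#'   network's gene order; isolated genes are kept.
#' @export
build_interaction_graph <- function(net, mode = c("essential", "syntactic")) {
  mode <- match.arg(mode)
  edges <- as_edge_list(net, mode = mode)
  g <- igraph::make_empty_graph(n = 0, directed = TRUE) +
    igraph::vertices(net$genes)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(edges$source, edges$target))
  }
  g
}

#' Vertex betweenness on the interaction graph
#'
#' For every node `g`, sums over ordered node pairs (both distinct from `g`)
#' the fraction of shortest directed paths between the pair that pass through
#' `g`. Unreachable pairs contribute nothing; self-loops are ignored for
#' path-finding.
#'
#' @param graph An interaction graph, see [build_interaction_graph()].
#' @return Named numeric vector of betweenness scores in vertex order.
#' @export
vertex_betweenness <- function(graph) {
  g <- igraph::simplify(graph, remove.loops = TRUE, remove.multiple = TRUE)
  vb <- igraph::betweenness(g, directed = TRUE, weights = NA)
  vb[igraph::V(graph)$name]
}

#' Connectivity z-scores
#'
#' Standardizes each node's total degree (in + out; a self-loop contributes
#' one to each). The standard variant centres by the mean and scales by the
#' sample standard deviation; the robust variant uses the median and the
#' median absolute deviation (scaled by 1.4826 for normal consistency).
#' When every node has the same degree the dispersion is zero and all z-scores
#' are defined as 0, with attribute `degenerate = TRUE`.
#'
#' @param graph An interaction graph.
#' @param robust Use median/MAD instead of mean/SD.
#' @param population Use the population (1/n) instead of the sample (1/(n-1))
#'   standard deviation. Ignored when `robust = TRUE`.
#' @return Named numeric vector of z-scores; attribute `degenerate` flags the
#'   zero-dispersion case.
#' @export
connectivity_zscore <- function(graph, robust = FALSE, population = FALSE) {
  if (igraph::vcount(graph) < 2) stop("need at least 2 nodes for a z-score")
  deg <- igraph::degree(graph, mode = "all", loops = TRUE)
  if (robust) {
    centre <- stats::median(deg)
    scale <- stats::mad(deg, constant = 1.4826)
  } else {
    centre <- mean(deg)
    scale <- if (population) sqrt(mean((deg - centre)^2)) else stats::sd(deg)
  }
  if (scale == 0) {
    z <- stats::setNames(rep(0, length(deg)), names(deg))
    attr(z, "degenerate") <- TRUE
    return(z)
  }
  z <- (deg - centre) / scale
  attr(z, "degenerate") <- FALSE
  z
}

#' Identify hub nodes
#'
#' Hubs are nodes whose connectivity z-score is at least 2.5 (boundary
#' included).
#'
#' @param z Named z-score vector from [connectivity_zscore()].
#' @param cutoff Hub threshold (default 2.5).
#' @return Character vector of hub gene names.
#' @export
identify_hubs <- function(z, cutoff = 2.5) {
  names(z)[z >= cutoff]
}
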