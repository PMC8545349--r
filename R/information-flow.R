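#' Enumerate simple directed paths between two genes
#'
#' All directed paths from `from` to `to` that visit no vertex twice, with at
#' most `max_len` edges, in a deterministic order (shorter paths first, then
#' lexicographic).
#'
#' @param graph An interaction graph.
#' @param from,to Distinct gene names.
#' @param max_len Maximum number of edges per path; `NULL` (default) leaves
#'   simple paths unbounded. Dense graphs can hold exponentially many simple
#'   paths — set a cap when enumeration is only needed up to a length.
#' @return List of character vectors (each a path of gene names, endpoints
#'   included); empty when `to` is unreachable.
#' @export
enumerate_simple_paths <- function(graph, from, to, max_len = NULL) {
  if (from == to) stop("`from` and `to` must differ")
  cutoff <- if (is.null(max_len)) -1 else max_len
  paths <- igraph::all_simple_paths(graph, from = from, to = to,
                                    mode = "out", cutoff = cutoff)
  paths <- lapply(paths, function(p) igraph::V(graph)$name[as.integer(p)])
  key <- vapply(paths, paste, character(1), collapse = "\r")
  paths[order(lengths(paths), key)]
}

#' Mean edge mutual information along a path
#'
#' The mutual information of every edge along the path
#' ([edge_mutual_information()]) averaged over the number of edges, giving a
#' per-path score in \[0, 1\].
#'
#' @param net A [boolean_network()].
#' @param path Character vector of genes; consecutive genes must be edges of
#'   the interaction graph.
#' @param bias State bias passed to [edge_mutual_information()].
#' @return A number in \[0, 1\].
#' @export
path_mutual_information <- function(net, path, bias = 0.5) {
  if (length(path) < 2) stop("a path needs at least one edge")
  mis <- vapply(seq_len(length(path) - 1), function(i) {
    edge_mutual_information(net, path[i], path[i + 1], bias = bias)
  }, numeric(1))
  mean(mis)
}

#' Maximal path mutual information from a non-hub to a hub
#'
#' Enumerates all simple paths between the pair and reports the best
#' normalized mutual information among them — the reliability of the most
#' reliable information channel from the start gene to the hub.
#'
#' @inheritParams path_mutual_information
#' @param from Start gene (a non-hub).
#' @param to End gene (a hub).
#' @param graph Interaction graph of `net` (recomputed when `NULL`).
#' @param max_len Maximum path length in edges, see [enumerate_simple_paths()].
#' @return One-row tibble: `start`, `end`, `max_mi`, `n_paths`. `max_mi` is
#'   `NA` when no path connects the pair (such pairs are dropped from group
#'   comparisons, not scored 0).
#' @export
max_path_mi <- function(net, from, to, graph = NULL, max_len = NULL, bias = 0.5) {
  if (is.null(graph)) graph <- build_interaction_graph(net)
  paths <- enumerate_simple_paths(graph, from, to, max_len = max_len)
  tibble::tibble(
    start = from, end = to,
    max_mi = if (length(paths) == 0) NA_real_ else
      max(vapply(paths, path_mutual_information, numeric(1), net = net, bias = bias)),
    n_paths = length(paths)
  )
}

#' Path-MI records for every (non-hub, hub) pair of a classified network
#'
#' For each pair of a non-hub start gene and a hub end gene, computes the
#' maximal simple-path mutual information and attaches the start gene's
#' screening class, producing the records compared across classes by
#' [compare_groups()]. Pairs without a connecting path are dropped.
#'
#' @param net A [boolean_network()].
#' @param classification Output of [classify_nodes()] for `net`.
#' @param max_len Maximum path length in edges (`NULL` = unbounded).
#' @param bias State bias for the edge mutual information.
#' @return Tibble: `start`, `end`, `class` (of the start gene), `max_mi`,
#'   `n_paths`.
#' @export
hub_path_records <- function(net, classification, max_len = NULL, bias = 0.5) {
  graph <- build_interaction_graph(net)
  hubs <- classification$gene[classification$hub]
  non_hubs <- classification$gene[!classification$hub]
  if (length(hubs) == 0 || length(non_hubs) == 0) {
    return(tibble::tibble(start = character(), end = character(),
                          class = factor(levels = c("PM", "NM", "NS")),
                          max_mi = numeric(), n_paths = integer()))
  }
  pairs <- tidyr::expand_grid(start = non_hubs, end = hubs)
  recs <- purrr::pmap(pairs, function(start, end) {
    max_path_mi(net, start, end, graph = graph, max_len = max_len, bias = bias)
  }) |> dplyr::bind_rows()
  recs$class <- classification$class[match(recs$start, classification$gene)]
  recs <- recs[!is.na(recs$max_mi), c("start", "end", "class", "max_mi", "n_paths")]
  tibble::as_tibble(recs)
}

#' Pairwise rank-sum comparison of path-MI groups
#'
#' Two-sided Wilcoxon rank-sum tests between every pair of groups, Bonferroni
#' corrected (raw p multiplied by the number of pairs, capped at 1). For small
#' groups the exact permutation null is enumerated with average ranks, so tied
#' data are handled exactly; larger groups use the normal approximation with
#' tie correction.
#'
#' @param records Tibble with a grouping column and a value column, e.g. the
#'   output of [hub_path_records()].
#' @param value,group Column names (strings) holding the values and group
#'   labels.
#' @param exact_limit Enumerate the exact null when `choose(n1 + n2, n1)` is
#'   at most this (default 20000).
#' @param alpha Significance level reported alongside (default 0.05).
#' @return Tibble: `group1`, `group2`, `n1`, `n2`, `p_raw`, `p_adj`,
#'   `significant`. Groups with fewer than 2 records are excluded with a
#'   warning.
#' @export
compare_groups <- function(records, value = "max_mi", group = "class",
                           exact_limit = 20000, alpha = 0.05) {
  vals <- split(records[[value]], droplevels(factor(records[[group]])))
  small <- names(vals)[lengths(vals) < 2]
  if (length(small) > 0) {
    warning("excluding group(s) with < 2 records: ", paste(small, collapse = ", "))
    vals <- vals[lengths(vals) >= 2]
  }
  if (length(vals) < 2) stop("need at least 2 groups with >= 2 records each")
  pairs <- utils::combn(names(vals), 2)
  n_pairs <- ncol(pairs)
  out <- purrr::map(seq_len(n_pairs), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    p <- rank_sum_test(vals[[g1]], vals[[g2]], exact_limit = exact_limit)
    tibble::tibble(group1 = g1, group2 = g2,
                   n1 = length(vals[[g1]]), n2 = length(vals[[g2]]),
                   p_raw = p)
  }) |> dplyr::bind_rows()
  out$p_adj <- pmin(out$p_raw * n_pairs, 1)
  out$significant <- out$p_adj < alpha
  attr(out, "alpha") <- alpha
  attr(out, "n_comparisons") <- n_pairs
  out
}

# Two-sided rank-sum p-value. Exact enumeration of the permutation null (on
# average ranks, so ties are exact) when feasible, else wilcox.test's normal
# approximation with tie correction.
rank_sum_test <- function(x, y, exact_limit = 20000) {
  n1 <- length(x); n2 <- length(y)
  if (choose(n1 + n2, n1) <= exact_limit) {
    pooled <- rank(c(x, y), ties.method = "average")
    obs <- sum(pooled[seq_len(n1)])
    centre <- n1 * (n1 + n2 + 1) / 2
    combos <- utils::combn(n1 + n2, n1)
    null_w <- colSums(matrix(pooled[combos], nrow = n1))
    mean(abs(null_w - centre) >= abs(obs - centre) - 1e-12)
  } else {
    suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided",
                         exact = FALSE, correct = TRUE)$p.value)
  }
}
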