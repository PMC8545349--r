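#' Score every gene of a network collection
#'
#' Computes the static scores and (optionally) the dynamic impact of every
#' gene in every network, stacked into one long table — the input of
#' [sensitivity_specificity_sweep()] and [screen_collection()].
#'
#' @param nets Named list of [boolean_network()] objects (see
#'   [read_boolnet_collection()], [generate_network_collection()]).
#' @param dynamics Compute the perturbation-based dynamic impact (`TRUE` by
#'   default; the static screen alone does not need it).
#' @param bias State bias for the determinative power.
#' @param mode,n_starts,seed,exhaustive_limit Attractor-search options, see
#'   [find_attractors()]. Networks larger than `exhaustive_limit` fall back to
#'   sampled search automatically when `seed` is given.
#' @return Tibble with one row per gene per network: `network`, `gene`, the
#'   [static_scores()] columns, and (when `dynamics`) the [dynamic_impact()]
#'   columns including `impact`.
#' @export
score_collection <- function(nets, dynamics = TRUE, bias = 0.5,
                             mode = c("exhaustive", "sampled"),
                             n_starts = NULL, seed = NULL,
                             exhaustive_limit = 25) {
  mode <- match.arg(mode)
  if (is.null(names(nets))) names(nets) <- sprintf("net%02d", seq_along(nets))
  purrr::imap(nets, function(net, nm) {
    stat <- static_scores(net, bias = bias)
    stat <- dplyr::mutate(stat, network = nm, .before = 1)
    if (!dynamics) return(stat)
    net_mode <- if (mode == "exhaustive" && length(net$genes) > exhaustive_limit &&
                    !is.null(seed)) "sampled" else mode
    dyn <- dynamic_impact(net, mode = net_mode, n_starts = n_starts,
                          seed = seed, exhaustive_limit = exhaustive_limit)
    dplyr::left_join(stat, dyn, by = "gene")
  }) |> dplyr::bind_rows()
}

#' Screen one network for dynamically relevant nodes
#'
#' The full single-model pipeline: static scores, selection at the threshold,
#' classification into hubs / gatekeepers (positive mismatches) / negative
#' mismatches / non-selected, input-node detection and, optionally, the
#' dynamic impact for comparison.
#'
#' @param net A [boolean_network()].
#' @param threshold Selection percentage `T` (default 73).
#' @param selector Selection set, see [classify_nodes()].
#' @param dynamics Also compute the perturbation-based dynamic impact.
#' @inheritParams score_collection
#' @return Tibble of class `bn_classification`: the [classify_nodes()] output
#'   plus `input_node` and, when `dynamics`, the dynamic measures.
#' @export
screen_network <- function(net, threshold = 73,
                           selector = c("intersection", "union", "vb", "dp"),
                           dynamics = TRUE, bias = 0.5,
                           mode = c("exhaustive", "sampled"),
                           n_starts = NULL, seed = NULL, exhaustive_limit = 25) {
  selector <- match.arg(selector)
  mode <- match.arg(mode)
  out <- classify_nodes(static_scores(net, bias = bias), threshold = threshold,
                        selector = selector)
  out$input_node <- out$gene %in% detect_input_nodes(net)
  if (dynamics) {
    dyn <- dynamic_impact(net, mode = mode, n_starts = n_starts, seed = seed,
                          exhaustive_limit = exhaustive_limit)
    out <- dplyr::left_join(out, dyn, by = "gene")
  }
  attr(out, "threshold") <- threshold
  attr(out, "selector") <- selector
  attr(out, "network") <- net$name
  class(out) <- c("bn_classification", class(out))
  out
}

#' Screen a collection of networks
#'
#' Runs the whole method over a model collection: per-network static scoring
#' and classification, dynamic impact, the sensitivity/specificity sweep
#' across thresholds, and (optionally) the comparator features. The result
#' carries broom-style [tidy()] and [glance()] methods and an
#' [ggplot2::autoplot()].
#'
#' @inheritParams score_collection
#' @param threshold Selection percentage `T` (default 73).
#' @param selector Selection set, see [classify_nodes()].
#' @param sweep Run the threshold sweep (needs `dynamics = TRUE`).
#' @param comparators Also compute canalysation, motifs and feedback vertex
#'   sets per network.
#' @param max_len Path-length cap for the hub path-MI records (`NULL` =
#'   unbounded simple paths).
#' @return Object of class `bn_screen` with elements `nodes` (per-gene
#'   tibble), `sweep` (`bn_sweep` or `NULL`), `path_mi` (hub path records),
#'   `comparators`, `threshold`, `selector`.
#' @export
screen_collection <- function(nets, threshold = 73,
                              selector = c("intersection", "union", "vb", "dp"),
                              dynamics = TRUE, sweep = dynamics,
                              comparators = FALSE, bias = 0.5,
                              mode = c("exhaustive", "sampled"),
                              n_starts = NULL, seed = NULL,
                              exhaustive_limit = 25, max_len = NULL) {
  selector <- match.arg(selector)
  mode <- match.arg(mode)
  if (is.null(names(nets))) names(nets) <- sprintf("net%02d", seq_along(nets))

  nodes <- purrr::imap(nets, function(net, nm) {
    cls <- screen_network(net, threshold = threshold, selector = selector,
                          dynamics = dynamics, bias = bias, mode = mode,
                          n_starts = n_starts, seed = seed,
                          exhaustive_limit = exhaustive_limit)
    dplyr::mutate(as_bare_tibble(cls), network = nm, .before = 1)
  }) |> dplyr::bind_rows()

  sweep_curve <- NULL
  if (sweep && dynamics) {
    sweep_curve <- sensitivity_specificity_sweep(nodes, selector = selector)
  }

  path_mi <- purrr::imap(nets, function(net, nm) {
    cls <- nodes[nodes$network == nm, ]
    recs <- hub_path_records(net, cls, max_len = max_len, bias = bias)
    if (nrow(recs) > 0) dplyr::mutate(recs, network = nm, .before = 1) else NULL
  }) |> dplyr::bind_rows()

  comp <- NULL
  if (comparators) {
    comp <- purrr::imap(nets, function(net, nm) {
      dplyr::mutate(comparator_report(net), network = nm, .before = 1)
    })
    totals <- purrr::map(comp, attr, "motif_totals")
    comp <- dplyr::bind_rows(comp)
    attr(comp, "motif_totals") <- Reduce(`+`, totals)
  }

  structure(list(nodes = nodes, sweep = sweep_curve, path_mi = path_mi,
                 comparators = comp, threshold = threshold,
                 selector = selector, n_networks = length(nets)),
            class = "bn_screen")
}

# Drop bookkeeping attributes (graphs, per-model metadata) so rows from
# different models stack cleanly.
as_bare_tibble <- function(x) {
  out <- tibble::as_tibble(x)
  for (a in setdiff(names(attributes(out)), c("names", "row.names", "class"))) {
    attr(out, a) <- NULL
  }
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' @export
print.bn_screen <- function(x, ...) {
  g <- glance(x)
  cat("<bn_screen> ", g$n_networks, " network(s), ", g$n_nodes, " genes; T = ",
      x$threshold, "%, selector = ", x$selector, "\n", sep = "")
  cat("  selected ", g$n_selected, " (PM ", g$n_pm, ", NM ", g$n_nm,
      "), NS ", g$n_ns, ", hubs ", g$n_hubs, ", input nodes ", g$n_inputs,
      "\n", sep = "")
  if (!is.null(x$sweep)) {
    cat("  sweep crossing: T = ", attr(x$sweep, "crossing_threshold"),
        "%, sensitivity ", round(attr(x$sweep, "crossing_sensitivity"), 3),
        ", specificity ", round(attr(x$sweep, "crossing_specificity"), 3),
        "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a screening result
#'
#' @param x A `bn_screen` object.
#' @param ... Unused.
#' @return The per-gene node table (one row per gene per network).
#' @export
tidy.bn_screen <- function(x, ...) x$nodes

#' One-row summary of a screening result
#'
#' @param x A `bn_screen` object.
#' @param ... Unused.
#' @return One-row tibble: collection-level counts and, when the sweep was
#'   run, the crossing threshold and the sensitivity/specificity there.
#' @export
glance.bn_screen <- function(x, ...) {
  n <- x$nodes
  out <- tibble::tibble(
    n_networks = x$n_networks,
    n_nodes = nrow(n),
    n_selected = sum(n$selected),
    n_pm = sum(n$class == "PM"),
    n_nm = sum(n$class == "NM"),
    n_ns = sum(n$class == "NS"),
    n_hubs = sum(n$hub),
    n_inputs = sum(n$input_node),
    threshold = x$threshold
  )
  if (!is.null(x$sweep)) {
    out$crossing_threshold <- attr(x$sweep, "crossing_threshold")
    out$crossing_sensitivity <- attr(x$sweep, "crossing_sensitivity")
    out$crossing_specificity <- attr(x$sweep, "crossing_specificity")
  }
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
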