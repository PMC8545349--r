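#' Canalysing-variable analysis
#'
#' An input of a Boolean function is canalysing when one of its values alone
#' fixes the function's output, whatever the other inputs do. A gene's
#' canalysation level is the number of functions across the network in which
#' it is canalysing; a gene with level >= 1 is a canalyser.
#'
#' @param net A [boolean_network()].
#' @return Tibble with one row per gene: `gene`, `level`, `canalyser`.
#' @examples
#' net <- parse_boolnet("targets, factors\nA, B | C\nB, A\nC, A & B")
#' canalysing_analysis(net)
#' @export
canalysing_analysis <- function(net) {
  level <- stats::setNames(integer(length(net$genes)), net$genes)
  for (g in net$genes) {
    f <- net$functions[[g]]
    k <- length(f$inputs)
    if (k == 0) next
    rows <- 0:(2^k - 1)
    for (i in seq_len(k)) {
      pos <- k - i
      canalysing <- any(vapply(c(0L, 1L), function(a) {
        vals <- f$table[rows[bit_at(rows, pos) == a] + 1L]
        all(vals == vals[1])
      }, logical(1)))
      if (canalysing) level[f$inputs[i]] <- level[f$inputs[i]] + 1L
    }
  }
  lvl <- unname(level[net$genes])
  tibble::tibble(gene = net$genes, level = lvl, canalyser = lvl >= 1L)
}

#' Infer regulatory signs of essential edges
#'
#' An edge `g -> g'` is positive when the target's function is non-decreasing
#' in `g` over every context of the remaining inputs, negative when
#' non-increasing, and ambivalent when neither (non-unate in `g`, e.g. XOR).
#'
#' @param net A [boolean_network()].
#' @return Tibble with columns `from`, `to`, `sign`
#'   (`"positive"`, `"negative"` or `"ambivalent"`), one row per essential
#'   edge.
#' @export
infer_edge_signs <- function(net) {
  rows_out <- purrr::map(net$genes, function(to) {
    f <- net$functions[[to]]
    ess <- essential_inputs(f)
    if (length(ess) == 0) return(NULL)
    k <- length(f$inputs)
    rows <- 0:(2^k - 1)
    signs <- vapply(ess, function(from) {
      pos <- k - match(from, f$inputs)
      lo <- rows[bit_at(rows, pos) == 0L]
      d <- f$table[bitwOr(lo, bitwShiftL(1L, pos)) + 1L] - f$table[lo + 1L]
      if (all(d >= 0)) "positive" else if (all(d <= 0)) "negative" else "ambivalent"
    }, character(1))
    tibble::tibble(from = ess, to = to, sign = unname(signs))
  })
  dplyr::bind_rows(rows_out)
}

#' Count feed-forward-loop and bifan motifs
#'
#' Feed-forward loops are ordered triples (X, Y, Z) of distinct nodes with
#' edges X->Y, Y->Z and X->Z; they are typed by edge sign (coherent type 1:
#' all three positive; incoherent type 1: X->Y and X->Z positive, Y->Z
#' negative); triples containing an ambivalent edge are not typed. A bifan is
#' an unordered pair of distinct sources jointly regulating an unordered pair
#' of distinct targets (four edges), counted once per node set. Self-loops
#' never participate in motifs.
#'
#' @param graph An interaction graph.
#' @param signs Edge sign tibble from [infer_edge_signs()]; required for FFL
#'   typing (bifans ignore signs).
#' @return List of class `bn_motifs`: `c1ffl`, `i1ffl`, `bifan` (counts) and
#'   `participation`, a tibble of per-gene motif membership counts.
#' @export
count_motifs <- function(graph, signs) {
  nodes <- igraph::V(graph)$name
  adj <- as.matrix(igraph::as_adjacency_matrix(
    igraph::simplify(graph, remove.loops = TRUE, remove.multiple = TRUE)))
  adj <- adj[nodes, nodes, drop = FALSE]
  sign_of <- function(from, to) {
    s <- signs$sign[signs$from == from & signs$to == to]
    if (length(s) == 0) NA_character_ else s
  }

  part <- matrix(0L, nrow = length(nodes), ncol = 3,
                 dimnames = list(nodes, c("c1ffl", "i1ffl", "bifan")))
  c1 <- 0L; i1 <- 0L
  for (x in nodes) for (y in nodes) {
    if (x == y || adj[x, y] == 0) next
    for (z in nodes) {
      if (z == x || z == y || adj[y, z] == 0 || adj[x, z] == 0) next
      sxy <- sign_of(x, y); syz <- sign_of(y, z); sxz <- sign_of(x, z)
      if (any(is.na(c(sxy, syz, sxz))) ||
          any(c(sxy, syz, sxz) == "ambivalent")) next
      if (sxy == "positive" && syz == "positive" && sxz == "positive") {
        c1 <- c1 + 1L
        part[c(x, y, z), "c1ffl"] <- part[c(x, y, z), "c1ffl"] + 1L
      } else if (sxy == "positive" && sxz == "positive" && syz == "negative") {
        i1 <- i1 + 1L
        part[c(x, y, z), "i1ffl"] <- part[c(x, y, z), "i1ffl"] + 1L
      }
    }
  }

  bifan <- 0L
  if (length(nodes) >= 2) {
    src_pairs <- utils::combn(nodes, 2)
    for (i in seq_len(ncol(src_pairs))) {
      x <- src_pairs[1, i]; y <- src_pairs[2, i]
      common <- nodes[adj[x, ] == 1 & adj[y, ] == 1]
      common <- setdiff(common, c(x, y))
      m <- length(common)
      if (m < 2) next
      n_here <- choose(m, 2)
      bifan <- bifan + n_here
      part[c(x, y), "bifan"] <- part[c(x, y), "bifan"] + n_here
      part[common, "bifan"] <- part[common, "bifan"] + (m - 1L)
    }
  }

  structure(list(
    c1ffl = c1, i1ffl = i1, bifan = as.integer(bifan),
    participation = tibble::tibble(
      gene = nodes,
      c1ffl = unname(part[, "c1ffl"]),
      i1ffl = unname(part[, "i1ffl"]),
      bifan = unname(part[, "bifan"])
    )
  ), class = "bn_motifs")
}

#' @export
print.bn_motifs <- function(x, ...) {
  cat("<bn_motifs> C1FFL:", x$c1ffl, " I1FFL:", x$i1ffl, " bifan:", x$bifan, "\n")
  invisible(x)
}

#' Feedback vertex set of the interaction graph
#'
#' A node set whose removal leaves the graph acyclic. Self-loop nodes are
#' always included. On small graphs the minimum set is found exactly by
#' searching subsets of increasing size over the cyclic core (after trimming
#' nodes that cannot lie on a cycle), with a deterministic lexicographic
#' tie-break; when the graph or the search budget is exceeded, a greedy
#' cycle-breaking heuristic is used and the result is flagged as possibly
#' non-minimum.
#'
#' @param graph A directed graph.
#' @param exact_limit Maximum cyclic-core size for the exact search
#'   (default 30).
#' @param max_subsets Work budget: maximum number of candidate subsets tested
#'   before falling back to the greedy heuristic.
#' @return Character vector of gene names, sorted; attribute `minimum` is
#'   `TRUE` when the exact search completed.
#' @examples
#' g <- igraph::graph_from_literal(A -+ B, B -+ A)
#' feedback_vertex_set(g)
#' @export
feedback_vertex_set <- function(graph, exact_limit = 30, max_subsets = 1e5) {
  is_loop <- igraph::which_loop(graph)
  loops <- unique(igraph::ends(graph, igraph::E(graph))[is_loop, 1])
  work <- igraph::delete_vertices(igraph::simplify(graph, remove.loops = TRUE),
                                  loops)
  core <- trim_acyclic_parts(work)

  fvs <- NULL
  minimum <- TRUE
  if (igraph::vcount(core) > 0) {
    if (igraph::vcount(core) <= exact_limit) {
      fvs <- exact_fvs(core, max_subsets)
      if (is.null(fvs)) minimum <- FALSE
    } else {
      minimum <- FALSE
    }
    if (is.null(fvs)) fvs <- greedy_fvs(core)
  }
  out <- sort(c(loops, fvs))
  # removal must always leave the graph acyclic
  remainder <- igraph::delete_vertices(graph, out)
  stopifnot(igraph::vcount(remainder) == 0 || igraph::is_dag(remainder))
  attr(out, "minimum") <- minimum
  out
}

# Iteratively drop vertices with no incoming or no outgoing edge; what
# remains contains every cycle of the graph.
trim_acyclic_parts <- function(g) {
  repeat {
    deg_in <- igraph::degree(g, mode = "in")
    deg_out <- igraph::degree(g, mode = "out")
    drop <- names(deg_in)[deg_in == 0 | deg_out == 0]
    if (length(drop) == 0) return(g)
    g <- igraph::delete_vertices(g, drop)
  }
}

# Minimum FVS by subset enumeration in lexicographic order; NULL when the
# work budget runs out.
exact_fvs <- function(core, max_subsets) {
  nodes <- sort(igraph::V(core)$name)
  tested <- 0L
  for (k in 0:length(nodes)) {
    sets <- utils::combn(nodes, k, simplify = FALSE)
    for (s in sets) {
      tested <- tested + 1L
      if (tested > max_subsets) return(NULL)
      if (igraph::is_dag(igraph::delete_vertices(core, s))) return(s)
    }
  }
  character(0)
}

# Greedy heuristic: repeatedly remove the vertex with the largest in*out
# degree product among the cyclic core, then re-trim.
greedy_fvs <- function(core) {
  removed <- character(0)
  g <- core
  repeat {
    g <- trim_acyclic_parts(g)
    if (igraph::vcount(g) == 0 || igraph::is_dag(g)) return(removed)
    score <- igraph::degree(g, mode = "in") * igraph::degree(g, mode = "out")
    pick <- sort(names(score)[score == max(score)])[1]
    removed <- c(removed, pick)
    g <- igraph::delete_vertices(g, pick)
  }
}

#' Per-network comparator report
#'
#' Combines the classic static features the screen is compared against —
#' canalysation levels, motif participation and feedback-vertex-set
#' membership — into one per-gene table.
#'
#' @param net A [boolean_network()].
#' @return Tibble: `gene`, `level`, `canalyser`, `c1ffl`, `i1ffl`, `bifan`,
#'   `fvs`. Motif totals and FVS minimality are kept as attributes.
#' @export
comparator_report <- function(net) {
  graph <- build_interaction_graph(net)
  can <- canalysing_analysis(net)
  motifs <- count_motifs(graph, infer_edge_signs(net))
  fvs <- feedback_vertex_set(graph)
  out <- dplyr::left_join(can, motifs$participation, by = "gene")
  out$fvs <- out$gene %in% fvs
  attr(out, "motif_totals") <- c(c1ffl = motifs$c1ffl, i1ffl = motifs$i1ffl,
                                 bifan = motifs$bifan)
  attr(out, "fvs_minimum") <- attr(fvs, "minimum")
  out
}
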