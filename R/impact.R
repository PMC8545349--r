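#' Dynamic impact of perturbing one gene
#'
#' Compares the attractor landscape of the network with the landscapes after
#' knocking the gene out (KO) and over-expressing it (OE). Attractors are
#' compared through their trinary summaries with the perturbed gene's own
#' component removed (reduced summaries, set semantics — duplicates arising
#' after the reduction collapse). Three measures are reported, each as the
#' maximum over the two perturbations:
#'
#' * **gain** — number of reduced summaries present after the perturbation but
#'   not before;
#' * **loss** — number of original reduced summaries with no match in the
#'   perturbed set;
#' * **shift** — mean, over the perturbed network's attractors, of the
#'   distance to the closest original attractor, where the distance sums the
#'   absolute trinary differences over all genes except the perturbed one.
#'
#' @param net A [boolean_network()].
#' @param gene The gene to perturb.
#' @param attractors Optional precomputed `bn_attractors` for `net` (avoids
#'   recomputation when screening many genes).
#' @inheritParams find_attractors
#' @return One-row tibble: `gene`, `gain`, `loss`, `shift`, and the per-
#'   perturbation values (`gain_ko`, `gain_oe`, ...).
#' @examples
#' net <- parse_boolnet("targets, factors\nA, C\nB, A & C\nC, !B")
#' perturbation_impact(net, "B")
#' @export
perturbation_impact <- function(net, gene, attractors = NULL,
                                mode = c("exhaustive", "sampled"),
                                n_starts = NULL, seed = NULL,
                                exhaustive_limit = 25) {
  mode <- match.arg(mode)
  if (!gene %in% net$genes) stop("unknown gene: ", gene)
  if (is.null(attractors)) {
    attractors <- find_attractors(net, mode = mode, n_starts = n_starts,
                                  seed = seed, exhaustive_limit = exhaustive_limit)
  }
  orig <- attractor_summaries(attractors)
  gi <- match(gene, net$genes)

  per <- lapply(c(KO = "KO", OE = "OE"), function(p) {
    pnet <- apply_perturbation(net, gene, p)
    patt <- find_attractors(pnet, mode = mode, n_starts = n_starts,
                            seed = seed, exhaustive_limit = exhaustive_limit)
    pert <- attractor_summaries(patt)
    orig_red <- unique_rows(orig[, -gi, drop = FALSE])
    pert_red <- unique_rows(pert[, -gi, drop = FALSE])
    ok <- row_keys(orig_red)
    pk <- row_keys(pert_red)
    # mean over perturbed attractors of the reduced distance to the closest
    # original attractor (perturbed gene excluded from the distance)
    shift <- mean(apply(pert[, -gi, drop = FALSE], 1, function(a_pert) {
      min(apply(orig[, -gi, drop = FALSE], 1, trinary_distance, a_pert))
    }))
    if (nrow(pert) == 0) shift <- 0
    list(gain = sum(!pk %in% ok), loss = sum(!ok %in% pk), shift = shift)
  })

  tibble::tibble(
    gene = gene,
    gain = max(per$KO$gain, per$OE$gain),
    loss = max(per$KO$loss, per$OE$loss),
    shift = max(per$KO$shift, per$OE$shift),
    gain_ko = per$KO$gain, gain_oe = per$OE$gain,
    loss_ko = per$KO$loss, loss_oe = per$OE$loss,
    shift_ko = per$KO$shift, shift_oe = per$OE$shift
  )
}

unique_rows <- function(m) m[!duplicated(row_keys(m)), , drop = FALSE]

# L1 distance between trinary summary vectors (terms in {0, 0.5, 1})
trinary_distance <- function(a, b) sum(abs(a - b))

row_keys <- function(m) {
  if (ncol(m) == 0) return(rep("", nrow(m)))
  apply(m, 1, paste, collapse = "|")
}

#' Dynamic impact table for every gene of a network
#'
#' Runs [perturbation_impact()] for each gene (sharing one attractor
#' computation for the unperturbed network) and aggregates the three measures
#' into the per-gene dynamic impact percentile via [dynamic_impact_ranking()].
#'
#' @inheritParams perturbation_impact
#' @return Tibble with one row per gene: the perturbation measures plus
#'   `impact`, the aggregated percentile in (0, 1].
#' @export
dynamic_impact <- function(net, mode = c("exhaustive", "sampled"),
                           n_starts = NULL, seed = NULL,
                           exhaustive_limit = 25) {
  mode <- match.arg(mode)
  attractors <- find_attractors(net, mode = mode, n_starts = n_starts,
                                seed = seed, exhaustive_limit = exhaustive_limit)
  rows <- purrr::map(net$genes, function(g) {
    perturbation_impact(net, g, attractors = attractors, mode = mode,
                        n_starts = n_starts, seed = seed,
                        exhaustive_limit = exhaustive_limit)
  })
  dynamic_impact_ranking(dplyr::bind_rows(rows))
}

#' Aggregate gain, loss and shift into a dynamic impact percentile
#'
#' Within a network, each of the three perturbation measures is ranked in
#' ascending order (larger measure, larger rank; ties share the average rank).
#' The dynamic impact of a gene is the mean of its three ranks divided by the
#' number of genes, a percentile in (0, 1].
#'
#' @param impacts Tibble with columns `gene`, `gain`, `loss`, `shift` — one
#'   row per gene of a single network.
#' @return The input with an `impact` column appended.
#' @export
dynamic_impact_ranking <- function(impacts) {
  if (nrow(impacts) == 0) stop("empty impact table")
  n <- nrow(impacts)
  rk <- function(x) rank(x, ties.method = "average")
  dplyr::mutate(impacts,
    impact = (rk(.data$gain) + rk(.data$loss) + rk(.data$shift)) / (3 * n))
}
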