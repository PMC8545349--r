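#' Top-scoring fraction of genes
#'
#' Selects the `ceiling(T * n / 100)` highest-scoring genes. Ties are broken
#' by a deterministic total order — score descending, then gene name
#' ascending — so the selected set always has exactly the prescribed size.
#'
#' @param scores Named numeric vector (names are genes).
#' @param threshold Percentage `T` in \[1, 100\].
#' @return Character vector of selected gene names.
#' @examples
#' top_fraction(c(a = 3, b = 1, c = 2, d = 1), 50)
#' @export
top_fraction <- function(scores, threshold) {
  if (length(scores) == 0) stop("empty score vector")
  if (threshold < 1 || threshold > 100) stop("`threshold` must be in [1, 100]")
  if (any(!is.finite(scores))) stop("scores must be finite")
  m <- ceiling(threshold * length(scores) / 100)
  ord <- order(-scores, names(scores))
  names(scores)[ord[seq_len(m)]]
}

#' Static selection sets at a threshold
#'
#' The screening's candidate sets: the top fraction by vertex betweenness,
#' the top fraction by determinative power, and their union and intersection.
#'
#' @param scores Static score tibble from [static_scores()] (or any tibble
#'   with `gene`, `vb`, `dp` columns).
#' @param threshold Selection percentage `T` (default 73).
#' @return List with elements `threshold`, `vb_top`, `dp_top`, `union`,
#'   `intersection`.
#' @export
static_selection <- function(scores, threshold = 73) {
  vb <- stats::setNames(scores$vb, scores$gene)
  dp <- stats::setNames(scores$dp, scores$gene)
  vb_top <- top_fraction(vb, threshold)
  dp_top <- top_fraction(dp, threshold)
  list(threshold = threshold,
       vb_top = vb_top,
       dp_top = dp_top,
       union = union(vb_top, dp_top),
       intersection = intersect(vb_top, dp_top))
}

selector_set <- function(selection, selector = c("intersection", "union", "vb", "dp")) {
  selector <- match.arg(selector)
  switch(selector,
         intersection = selection$intersection,
         union = selection$union,
         vb = selection$vb_top,
         dp = selection$dp_top)
}

percentile_rank <- function(x) rank(x, ties.method = "average") / length(x)

#' Classify genes into hubs, gatekeepers and negative mismatches
#'
#' Genes selected by the static screen (by default the intersection of the
#' top-`T` vertex-betweenness and determinative-power sets) are split by
#' comparing their within-network percentile ranks: a **positive mismatch**
#' (gatekeeper) ranks higher on the average of the two static measures than on
#' connectivity; a **negative mismatch** does not. Unselected genes are
#' labelled `NS`. The hub flag (connectivity z-score >= 2.5) is orthogonal to
#' the partition.
#'
#' @param scores Static score tibble from [static_scores()].
#' @param threshold Selection percentage `T` (default 73).
#' @param selector Which selection set defines "selected":
#'   `"intersection"` (default), `"union"`, `"vb"` or `"dp"`.
#' @param robust Use the robust (median/MAD) z-score for the hub flag.
#' @return The input tibble with columns `vb_pct`, `dp_pct`, `static_pct`,
#'   `conn_pct`, `selected`, `class` (`"PM"`, `"NM"` or `"NS"`) and `hub`
#'   appended/updated.
#' @export
classify_nodes <- function(scores, threshold = 73,
                           selector = c("intersection", "union", "vb", "dp"),
                           robust = FALSE) {
  selector <- match.arg(selector)
  sel <- selector_set(static_selection(scores, threshold), selector)
  out <- dplyr::mutate(scores,
    vb_pct = percentile_rank(.data$vb),
    dp_pct = percentile_rank(.data$dp),
    conn_pct = percentile_rank(.data$degree),
    static_pct = (.data$vb_pct + .data$dp_pct) / 2,
    selected = .data$gene %in% sel,
    hub = (if (robust) .data$z_robust else .data$z) >= 2.5,
    class = dplyr::case_when(
      !selected ~ "NS",
      static_pct > conn_pct ~ "PM",
      TRUE ~ "NM"
    )
  )
  out$class <- factor(out$class, levels = c("PM", "NM", "NS"))
  out
}

#' Detect input nodes
#'
#' Input nodes carry signals into the model without being regulated by it:
#' genes whose function has no essential input (constants), or whose only
#' essential input is themselves through the identity function (the common
#' `g, g` idiom for external inputs). A self-negating gene is *not* an input
#' node — it is a self-regulated oscillator.
#'
#' @param net A [boolean_network()].
#' @return Character vector of input-node names.
#' @export
detect_input_nodes <- function(net) {
  is_input <- vapply(net$genes, function(g) {
    f <- net$functions[[g]]
    ess <- essential_inputs(f)
    if (length(ess) == 0) return(TRUE)
    if (!identical(ess, g)) return(FALSE)
    # identity on self: output always equals the gene's own bit
    k <- length(f$inputs)
    pos <- k - match(g, f$inputs)  # bit position of g
    all(f$table == bit_at(0:(2^k - 1), pos))
  }, logical(1))
  net$genes[is_input]
}

#' Sensitivity/specificity of the static screen across thresholds
#'
#' At every threshold `T`, genes in the top `ceiling(T n / 100)` by dynamic
#' impact are the positive labels and the static selection (intersection of
#' the top vertex-betweenness and determinative-power sets, by default) is the
#' prediction. Sensitivity and specificity are computed per network and then
#' averaged across the collection (macro average); the crossing threshold is
#' the `T` where mean sensitivity and mean specificity are closest (ties go to
#' the smaller `T`).
#'
#' @param node_data Tibble with one row per gene per network and columns
#'   `network`, `gene`, `vb`, `dp`, `impact` (see [score_collection()]).
#' @param thresholds Integer thresholds to sweep (default `1:100`).
#' @param selector Prediction set: `"intersection"` (default), `"union"`,
#'   `"vb"` or `"dp"`.
#' @return Tibble of class `bn_sweep`: `threshold`, `sensitivity`,
#'   `specificity`, their standard deviations across networks, and
#'   `n_networks`. Attributes: `crossing_threshold` (and the sensitivity/
#'   specificity there) and `per_network`, the unaveraged values.
#' @export
sensitivity_specificity_sweep <- function(node_data, thresholds = 1:100,
                                          selector = c("intersection", "union", "vb", "dp")) {
  selector <- match.arg(selector)
  needed <- c("network", "gene", "vb", "dp", "impact")
  if (!all(needed %in% names(node_data))) {
    stop("`node_data` needs columns: ", paste(needed, collapse = ", "))
  }
  bad <- unique(node_data$network[!is.finite(node_data$impact)])
  if (length(bad) > 0) {
    warning("excluding network(s) with undefined dynamic scores: ",
            paste(bad, collapse = ", "))
    node_data <- node_data[!node_data$network %in% bad, ]
  }
  nets <- split(node_data, node_data$network)

  per_network <- purrr::map(nets, function(df) {
    vb <- stats::setNames(df$vb, df$gene)
    dp <- stats::setNames(df$dp, df$gene)
    imp <- stats::setNames(df$impact, df$gene)
    purrr::map(thresholds, function(T) {
      predicted <- selector_set(
        list(vb_top = top_fraction(vb, T), dp_top = top_fraction(dp, T),
             union = union(top_fraction(vb, T), top_fraction(dp, T)),
             intersection = intersect(top_fraction(vb, T), top_fraction(dp, T))),
        selector)
      labelled <- top_fraction(imp, T)
      pos <- df$gene %in% labelled
      pred <- df$gene %in% predicted
      tp <- sum(pos & pred); fn <- sum(pos & !pred)
      tn <- sum(!pos & !pred); fp <- sum(!pos & pred)
      tibble::tibble(
        network = df$network[1], threshold = T,
        sensitivity = if (tp + fn == 0) 1 else tp / (tp + fn),
        specificity = if (tn + fp == 0) 1 else tn / (tn + fp)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  curve <- per_network |>
    dplyr::group_by(.data$threshold) |>
    dplyr::summarise(
      sensitivity_sd = stats::sd(.data$sensitivity),
      specificity_sd = stats::sd(.data$specificity),
      sensitivity = mean(.data$sensitivity),
      specificity = mean(.data$specificity),
      n_networks = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select("threshold", "sensitivity", "specificity",
                  "sensitivity_sd", "specificity_sd", "n_networks")

  gap <- abs(curve$sensitivity - curve$specificity)
  cross_i <- which(gap == min(gap))[1]  # ties -> smaller threshold
  attr(curve, "crossing_threshold") <- curve$threshold[cross_i]
  attr(curve, "crossing_sensitivity") <- curve$sensitivity[cross_i]
  attr(curve, "crossing_specificity") <- curve$specificity[cross_i]
  attr(curve, "per_network") <- per_network
  attr(curve, "selector") <- selector
  class(curve) <- c("bn_sweep", class(curve))
  curve
}
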