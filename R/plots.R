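#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a sensitivity/specificity sweep
#'
#' Mean sensitivity and specificity across networks at every threshold, with
#' one-standard-deviation ribbons and a mark at the crossing threshold.
#'
#' @param object A `bn_sweep` from [sensitivity_specificity_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bn_sweep <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("sensitivity", "specificity"),
                        names_to = "measure", values_to = "value") |>
    dplyr::mutate(sd = ifelse(.data$measure == "sensitivity",
                              .data$sensitivity_sd, .data$specificity_sd))
  cross <- attr(object, "crossing_threshold")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$value,
                                   colour = .data$measure,
                                   fill = .data$measure)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$value - .data$sd, 0),
                                      ymax = pmin(.data$value + .data$sd, 1)),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = cross, linetype = "dashed") +
    ggplot2::labs(x = "selection threshold T (%)", y = NULL,
                  title = "Static screen vs dynamic impact",
                  subtitle = paste0("crossing at T = ", cross, "%")) +
    ggplot2::theme_minimal()
}

#' Plot a screening result
#'
#' Percentile distributions by node class: dynamic impact, static (VB/DP
#' average) and connectivity percentiles, with hubs pulled out of the
#' positive/negative-mismatch partition as their own display group.
#'
#' @param object A `bn_screen` from [screen_collection()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bn_screen <- function(object, ...) {
  nodes <- object$nodes |>
    dplyr::mutate(group = factor(
      ifelse(.data$hub, "hub", as.character(.data$class)),
      levels = c("hub", "PM", "NM", "NS")))
  long <- nodes |>
    dplyr::select("group", static = "static_pct", connectivity = "conn_pct",
                  dplyr::any_of(c(dynamic = "impact"))) |>
    tidyr::pivot_longer(-"group", names_to = "measure", values_to = "percentile")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$percentile,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~measure) +
    ggplot2::labs(x = NULL, y = "within-network percentile") +
    ggplot2::theme_minimal()
}

#' Plot path mutual information by start-node class
#'
#' Distribution of the maximal simple-path mutual information towards hubs,
#' split by the screening class of the start node.
#'
#' @param records Path-MI records, e.g. `screen$path_mi` from
#'   [screen_collection()] or [hub_path_records()].
#' @return A ggplot.
#' @export
plot_path_mi <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$class, y = .data$max_mi,
                                        fill = .data$class)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = "start-node class",
                  y = "max normalized path MI to hubs") +
    ggplot2::theme_minimal()
}
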