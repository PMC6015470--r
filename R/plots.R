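#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the hub-classification plane
#'
#' Scatter of each OTU's mean standardized local betweenness against its
#' standardized metacommunity betweenness, with the classification threshold
#' drawn as quadrant lines and points coloured by category.
#'
#' @param object A [hub_classification()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hub_classification <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot(object, aes(x = .data$mean_b_local, y = .data$b_meta,
                     colour = .data$category)) +
    geom_hline(yintercept = thr, linetype = "dashed", colour = "grey50") +
    geom_vline(xintercept = thr, linetype = "dashed", colour = "grey50") +
    geom_point(alpha = 0.7) +
    scale_colour_manual(values = c(
      metacommunity_hub = "#d73027", metacommunity_connector = "#fc8d59",
      local_hub = "#4575b4", peripheral = "grey60"
    ), drop = FALSE) +
    coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "mean standardized local betweenness",
         y = "standardized metacommunity betweenness",
         colour = NULL) +
    theme_minimal()
}

#' Plot a bipartite association network
#'
#' Simple two-row layout: plant nodes on top, fungal OTUs below, one segment
#' per association. Intended for small graphs and quick inspection, not for
#' publication-grade force-directed layouts.
#'
#' @param object An `assoc_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.assoc_graph <- function(object, ...) {
  edges <- tidy(object)
  plants <- sort(unique(edges$plant))
  fungi <- sort(unique(edges$fungus))
  pos <- dplyr::bind_rows(
    tibble(node = plants, x = seq_along(plants) / (length(plants) + 1), y = 1,
           partition = "plant"),
    tibble(node = fungi, x = seq_along(fungi) / (length(fungi) + 1), y = 0,
           partition = "fungus")
  )
  seg <- edges |>
    dplyr::left_join(dplyr::select(pos, "node", px = "x"),
                     by = c(plant = "node")) |>
    dplyr::left_join(dplyr::select(pos, "node", fx = "x"),
                     by = c(fungus = "node"))
  ggplot() +
    geom_segment(data = seg,
                 aes(x = .data$px, y = 1, xend = .data$fx, yend = 0,
                     linewidth = .data$weight),
                 alpha = 0.4, colour = "grey40") +
    scale_linewidth_continuous(range = c(0.2, 1.2), guide = "none") +
    geom_point(data = pos,
               aes(x = .data$x, y = .data$y, colour = .data$partition),
               size = 2) +
    scale_colour_manual(values = c(plant = "#1b7837", fungus = "#762a83")) +
    labs(x = NULL, y = NULL, colour = NULL) +
    theme_void()
}

#' Plot per-site composition of annotation groups
#'
#' Stacked-bar chart of group proportions per site, the graphical counterpart
#' of [composition_table()].
#'
#' @inheritParams composition_table
#' @return A ggplot object.
#' @export
plot_composition <- function(x, mapping) {
  comp <- composition_table(x, mapping)
  ggplot(comp, aes(x = .data$site, y = .data$proportion,
                   fill = .data$group)) +
    geom_col() +
    labs(x = NULL, y = "proportion of reads", fill = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
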