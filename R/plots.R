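#' Plot a Mapper graph
#'
#' Force-directed (Fruchterman-Reingold) layout with node area proportional
#' to member count, optionally colored by paradigm dominance.
#'
#' @param object A `mapper_graph`.
#' @param dominance Optional tibble from [label_nodes()] used to color
#'   nodes.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mapper_graph <- function(object, dominance = NULL, seed = 1L, ...) {
  g <- object$graph
  xy <- withr::with_seed(as.integer(seed),
                         igraph::layout_with_fr(g))
  nodes <- tibble(node = seq_len(igraph::vcount(g)),
                  x = xy[, 1], y = xy[, 2], size = igraph::V(g)$size)
  if (!is.null(dominance)) {
    nodes <- left_join(nodes, dominance[c("node", "label")], by = "node")
  } else {
    nodes$label <- "node"
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- tibble(x = nodes$x[el[, 1]], y = nodes$y[el[, 1]],
                  xend = nodes$x[el[, 2]], yend = nodes$y[el[, 2]])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          linewidth = 0.2, alpha = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$size,
                                     colour = .data$label)) +
    ggplot2::scale_size_area(max_size = 6) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "dominant paradigm", size = "members")
}

#' Scatter plot of a 2D embedding colored by paradigm
#'
#' The pre-Mapper view of the time points after dimension reduction.
#'
#' @param embedding A `mapper_embedding`.
#' @param paradigm Optional per-time-point paradigm labels.
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, paradigm = NULL) {
  stopifnot(inherits(embedding, "mapper_embedding"))
  df <- as_tibble(embedding$coords)
  names(df) <- c("dim1", "dim2")
  df$paradigm <- paradigm %||% "all"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                   colour = .data$paradigm)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = paste0(embedding$method, " 1"),
                  y = paste0(embedding$method, " 2"))
}

#' Modularity distributions across the parameter sweep
#'
#' Box plots of per-subject modularity per parameter triple, faceted by
#' interval count.
#'
#' @param sweep A `mapper_sweep` from [run_sweep()].
#' @return A ggplot object.
#' @export
plot_modularity_sweep <- function(sweep) {
  stopifnot(inherits(sweep, "mapper_sweep"))
  df <- sweep$manifest |>
    filter(.data$status == "ok") |>
    mutate(triple = sprintf("%d-%d-%d", as.integer(.data$n_intervals),
                            as.integer(.data$overlap_pct),
                            as.integer(.data$n_clusters)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$triple, y = .data$modularity)) +
    ggplot2::geom_boxplot() +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1)) +
    ggplot2::labs(x = "parameter triple (intervals-overlap-clusters)",
                  y = "modularity Q")
}
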