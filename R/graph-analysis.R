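#' Label Mapper nodes by paradigm dominance
#'
#' Each node takes the paradigm label held by the strict majority of its
#' member time points, with the majority fraction; an exact tie is labeled
#' `"TIE"` with the top fraction.
#'
#' @param graph A `mapper_graph`.
#' @param labels Character vector of paradigm labels indexed by time index
#'   (as used in the node member sets), e.g. the `paradigm` track of the
#'   [analysis_matrix()] the graph was built from.
#' @return A tibble `node`, `label`, `fraction`, `size`.
#' @examples
#' g <- build_nerve(list(c(1, 2, 3), c(3, 4)))
#' label_nodes(g, c("wm", "wm", "sm", "sm"))
#' @export
label_nodes <- function(graph, labels) {
  stopifnot(inherits(graph, "mapper_graph"))
  labels <- as.character(labels)
  idx_max <- max(unlist(graph$nodes$members))
  if (idx_max > length(labels) || anyNA(labels)) {
    abort("every member time index must carry a paradigm label.",
          class = "data_error")
  }
  res <- purrr::map(graph$nodes$members, function(mem) {
    counts <- sort(table(labels[mem]), decreasing = TRUE)
    top <- counts[1] / length(mem)
    lab <- if (length(counts) > 1 && counts[1] == counts[2]) "TIE" else
      names(counts)[1]
    list(label = lab, fraction = as.numeric(top))
  })
  tibble(node = graph$nodes$node,
         label = purrr::map_chr(res, "label"),
         fraction = purrr::map_dbl(res, "fraction"),
         size = graph$nodes$size)
}

#' Node centrality scores of a Mapper graph
#'
#' Standard normalized definitions: degree `deg / (n - 1)`; eigenvector
#' centrality scaled to unit maximum; pair-normalized shortest-path
#' betweenness; closeness `(n - 1) / sum of distances`.  Closeness and
#' eigenvector centrality require a connected graph; by default a
#' disconnected graph is restricted to its largest connected component with
#' a warning (`on_disconnected = "error"` raises instead), mirroring the
#' practice of choosing cover parameters that keep the graph connected.
#'
#' @param graph A `mapper_graph` or igraph object.
#' @param measure One of `"degree"`, `"eigenvector"`, `"betweenness"`,
#'   `"closeness"`.
#' @param on_disconnected `"largest_component"` (default) or `"error"`.
#' @return A tibble `node`, `score` covering the analysed component.
#' @examples
#' g <- build_nerve(list(c(1, 2), c(2, 3), c(3, 4)))
#' node_centrality(g, "closeness")
#' @export
node_centrality <- function(graph,
                            measure = c("degree", "eigenvector",
                                        "betweenness", "closeness"),
                            on_disconnected = c("largest_component", "error")) {
  measure <- match.arg(measure)
  on_disconnected <- match.arg(on_disconnected)
  g <- as_igraph(graph)
  comp <- analysis_component(g, on_disconnected)
  g <- comp$graph
  n <- igraph::vcount(g)
  score <- if (n == 1) {
    0
  } else {
    switch(measure,
      degree = igraph::degree(g) / (n - 1),
      eigenvector = igraph::eigen_centrality(g, scale = TRUE)$vector,
      betweenness = igraph::betweenness(g, normalized = TRUE),
      closeness = igraph::closeness(g, normalized = TRUE))
  }
  tibble(node = comp$nodes, score = as.numeric(score))
}

as_igraph <- function(graph) {
  if (inherits(graph, "mapper_graph")) graph$graph
  else if (inherits(graph, "igraph")) graph
  else abort("`graph` must be a mapper_graph or igraph object.")
}

analysis_component <- function(g, on_disconnected = "largest_component") {
  comp <- igraph::components(g)
  nodes <- seq_len(igraph::vcount(g))
  if (comp$no > 1) {
    if (on_disconnected == "error") {
      abort("Mapper graph is disconnected.", class = "disconnected_graph")
    }
    warn(sprintf(
      "Mapper graph has %d components; restricting analysis to the largest (%d of %d nodes).",
      comp$no, max(comp$csize), igraph::vcount(g)))
    keep <- unname(which(comp$membership == which.max(comp$csize)))
    g <- igraph::induced_subgraph(g, keep)
    nodes <- keep
  }
  list(graph = g, nodes = nodes)
}

#' Per-paradigm mean node centrality
#'
#' Arithmetic mean of node centrality scores over the nodes dominated by
#' each paradigm; TIE nodes are counted but excluded from every mean.  A
#' paradigm in `paradigms` with no dominated node gets an `NA` mean and a
#' warning (the comparison for that subject is undefined).
#'
#' @param scores Tibble `node`, `score` from [node_centrality()].
#' @param dominance Tibble from [label_nodes()].
#' @param paradigms Optional character vector of paradigms that must appear;
#'   defaults to the non-TIE labels present.
#' @param subject,measure Optional identifiers carried into the output.
#' @return A tibble `subject`, `measure`, `label`, `n_nodes`, `mean_score`.
#' @export
paradigm_mean_centrality <- function(scores, dominance, paradigms = NULL,
                                     subject = NA_character_,
                                     measure = NA_character_) {
  joined <- dplyr::inner_join(scores, dominance, by = "node")
  paradigms <- paradigms %||% setdiff(unique(dominance$label), "TIE")
  means <- joined |>
    filter(.data$label != "TIE") |>
    group_by(.data$label) |>
    summarise(n_nodes = n(), mean_score = mean(.data$score), .groups = "drop")
  out <- tibble(label = paradigms) |>
    left_join(means, by = "label") |>
    mutate(n_nodes = dplyr::coalesce(.data$n_nodes, 0L))
  if (any(is.na(out$mean_score))) {
    warn(paste0("no dominated nodes for paradigm(s): ",
                paste(out$label[is.na(out$mean_score)], collapse = ", "),
                "; mean undefined."))
  }
  n_tie <- sum(dominance$label == "TIE")
  dplyr::bind_cols(tibble(subject = subject, measure = measure), out) |>
    mutate(n_tie = n_tie)
}

#' Detect communities by greedy modularity maximization
#'
#' Agglomerative (fast-greedy) modularity optimization on the unweighted
#' nerve graph; the algorithm is deterministic, the `seed` argument is kept
#' for interface stability with stochastic optimizers.  The trivial
#' one-community partition (`Q = 0`) is always included as a candidate cut,
#' so the returned partition never has negative modularity.  An edgeless
#' graph yields one community per node.
#'
#' @param graph A `mapper_graph` or igraph object.
#' @param seed Unused by the deterministic greedy optimizer.
#' @return A tibble `node`, `community`.
#' @examples
#' g <- build_nerve(list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
#' detect_communities(g)
#' @export
detect_communities <- function(graph, seed = 1L) {
  g <- as_igraph(graph)
  if (igraph::ecount(g) == 0) {
    inform("edgeless graph: every node is its own community.")
    return(tibble(node = seq_len(igraph::vcount(g)),
                  community = seq_len(igraph::vcount(g))))
  }
  cl <- igraph::cluster_fast_greedy(igraph::simplify(g))
  mem <- as.integer(igraph::membership(cl))
  if (igraph::modularity(g, mem) < 0) mem <- rep(1L, igraph::vcount(g))
  tibble(node = seq_len(igraph::vcount(g)), community = mem)
}

#' Newman modularity of a partition
#'
#' `Q = (1 / 2m) * sum_ij (A_ij - k_i k_j / 2m) * delta(c_i, c_j)` for the
#' unweighted nerve graph; `Q` lies in `[-0.5, 1]`.  An edgeless graph has
#' `Q = 0` by convention (logged).
#'
#' @param graph A `mapper_graph` or igraph object.
#' @param partition Tibble `node`, `community` (as from
#'   [detect_communities()]) or a membership vector over all nodes.
#' @return The modularity score, a single number.
#' @examples
#' g <- build_nerve(list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
#' graph_modularity(g, detect_communities(g))
#' @export
graph_modularity <- function(graph, partition) {
  g <- as_igraph(graph)
  n <- igraph::vcount(g)
  membership <- if (is.data.frame(partition)) {
    if (!all(seq_len(n) %in% partition$node)) {
      abort("partition must cover every node.", class = "usage_error")
    }
    partition$community[match(seq_len(n), partition$node)]
  } else {
    if (length(partition) != n || anyNA(partition)) {
      abort("partition must cover every node.", class = "usage_error")
    }
    partition
  }
  if (igraph::ecount(g) == 0) {
    inform("edgeless graph: modularity defined as 0 by convention.")
    return(0)
  }
  igraph::modularity(g, as.integer(factor(membership)))
}
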