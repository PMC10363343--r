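#' Build the overlapping rectangular cover of a 2D embedding
#'
#' Per filter dimension the coordinate range `R` is covered by `n` closed
#' intervals of equal length `L = R / (n - (n - 1) * o)` with
#' `o = overlap_pct / 100`; interval `k` (0-based) starts at
#' `min + k * L * (1 - o)`, so consecutive intervals overlap by exactly
#' `o * L` and the union of intervals equals the range.  The 2D bins are all
#' `n^2` cross-products of the two dimensions' intervals, and a point
#' belongs to a bin when its coordinates lie inside the bin's closed bounds
#' in every dimension (boundary points belong to both neighbouring bins).
#' A dimension whose coordinates are all equal collapses to a single
#' interval with a warning.
#'
#' @param embedding A `mapper_embedding` (or bare n x 2 matrix).
#' @param n_intervals Number of intervals per dimension.
#' @param overlap_pct Overlap percentage in (0, 100).
#' @return A tibble of cover bins: `bin` id, interval indices `ix`/`iy`,
#'   closed bounds `xmin`/`xmax`/`ymin`/`ymax` and a `members` list-column
#'   of time-point indices.  Interval geometry is kept in attribute
#'   `intervals`.
#' @examples
#' emb <- structure(list(coords = cbind(runif(30), runif(30))),
#'                  class = "mapper_embedding")
#' cov <- build_cover(emb, 3, 40)
#' nrow(cov)
#' @export
build_cover <- function(embedding, n_intervals, overlap_pct) {
  coords <- if (inherits(embedding, "mapper_embedding")) embedding$coords else embedding
  stopifnot(is.matrix(coords), ncol(coords) == 2)
  if (!nrow(coords)) abort("embedding is empty.")
  o <- overlap_pct / 100
  stopifnot(o > 0, o < 1, n_intervals >= 1)

  axis_intervals <- function(v, dim_name) {
    lo <- min(v); hi <- max(v); R <- hi - lo
    if (R == 0) {
      warn(paste0("degenerate coordinate range in ", dim_name,
                  "; collapsing to a single interval."))
      return(tibble(k = 1L, start = lo, end = hi))
    }
    n <- n_intervals
    L <- R / (n - (n - 1) * o)
    start <- lo + (seq_len(n) - 1) * L * (1 - o)
    end <- start + L
    end[n] <- hi  # guard the top boundary against round-off
    tibble(k = seq_len(n), start = start, end = end)
  }
  ix <- axis_intervals(coords[, 1], "dimension 1")
  iy <- axis_intervals(coords[, 2], "dimension 2")

  bins <- tidyr::expand_grid(ix = ix$k, iy = iy$k)
  bins$bin <- seq_len(nrow(bins))
  bins$xmin <- ix$start[bins$ix]; bins$xmax <- ix$end[bins$ix]
  bins$ymin <- iy$start[bins$iy]; bins$ymax <- iy$end[bins$iy]
  bins$members <- purrr::map(seq_len(nrow(bins)), function(b) {
    which(coords[, 1] >= bins$xmin[b] & coords[, 1] <= bins$xmax[b] &
            coords[, 2] >= bins$ymin[b] & coords[, 2] <= bins$ymax[b])
  })
  out <- bins |> select("bin", "ix", "iy", "xmin", "xmax", "ymin", "ymax",
                        "members")
  attr(out, "intervals") <- list(x = ix, y = iy)
  out
}

#' Single-linkage clustering of one bin's preimage
#'
#' Clusters the bin's member time points by single-linkage agglomeration
#' under the Euclidean metric in the original channel space (not the 2D
#' embedding), cutting the dendrogram at `min(n_clusters, bin size)`
#' clusters.  Singleton bins yield one singleton cluster.
#'
#' @param bin_data Numeric matrix of the bin members' channel-space rows.
#' @param n_clusters Requested number of clusters.
#' @return A list of integer vectors partitioning `seq_len(nrow(bin_data))`.
#' @examples
#' cluster_bin(matrix(c(0, 1, 10, 11)), 2)
#' @export
cluster_bin <- function(bin_data, n_clusters) {
  if (is.null(dim(bin_data))) bin_data <- matrix(bin_data, ncol = 1)
  n <- nrow(bin_data)
  if (!n) abort("bin is empty.")
  if (n == 1) return(list(1L))
  k <- min(as.integer(n_clusters), n)
  hc <- hclust(dist(bin_data, method = "euclidean"), method = "single")
  assign <- cutree(hc, k = k)
  unname(split(seq_len(n), assign))
}

#' Build the nerve graph of a cluster collection
#'
#' One node per cluster; an unweighted undirected edge joins two nodes
#' whenever their member sets share at least one time index.  No self-loops,
#' no duplicate edges.
#'
#' @param clusters List of integer vectors of member time indices (all bins'
#'   clusters concatenated).
#' @param params Optional [mapper_params()] stamped on the graph.
#' @param bin_ids Optional integer vector recording each cluster's source
#'   bin.
#' @param n_points Total number of time points the clusters were drawn
#'   from; defaults to the largest index seen.
#' @return A `mapper_graph`: list with the igraph `graph`, a `nodes` tibble
#'   (`node`, `bin`, `size`, `members` list-column), `params` and
#'   `n_points`.
#' @examples
#' g <- build_nerve(list(c(1, 2), c(2, 3), 4))
#' igraph::ecount(g$graph)
#' @export
build_nerve <- function(clusters, params = NULL, bin_ids = NULL,
                        n_points = NULL) {
  if (!length(clusters)) abort("`clusters` must be nonempty.")
  clusters <- purrr::map(clusters, as.integer)
  k <- length(clusters)
  bin_ids <- bin_ids %||% rep(NA_integer_, k)
  n_points <- n_points %||% max(unlist(clusters))

  # invert membership: for every time index, the nodes containing it
  owner_of <- split(rep(seq_len(k), lengths(clusters)), unlist(clusters))
  pair_lists <- lapply(owner_of, function(nodes) {
    if (length(nodes) < 2) return(NULL)
    t(utils::combn(sort(nodes), 2))
  })
  edge_mat <- do.call(rbind, pair_lists)
  edge_mat <- if (is.null(edge_mat)) matrix(integer(), ncol = 2) else
    unique(edge_mat)

  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  if (nrow(edge_mat)) {
    g <- igraph::add_edges(g, t(edge_mat))
    g <- igraph::simplify(g)
  }
  igraph::V(g)$name <- as.character(seq_len(k))
  igraph::V(g)$size <- lengths(clusters)
  igraph::V(g)$bin <- bin_ids

  structure(
    list(graph = g,
         nodes = tibble(node = seq_len(k), bin = bin_ids,
                        size = lengths(clusters), members = clusters),
         params = params,
         n_points = as.integer(n_points)),
    class = "mapper_graph"
  )
}

#' @export
print.mapper_graph <- function(x, ...) {
  cat(sprintf("<mapper_graph> %d nodes, %d edges over %d time points\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$n_points))
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' Run the full Mapper construction
#'
#' Composition of [compute_filter()], [build_cover()], per-bin
#' [cluster_bin()] in the original channel space, and [build_nerve()].
#' Deterministic given the matrix, parameters and filter seed.  Empty bins
#' are skipped silently; every time point appears in at least one node
#' because the cover spans the whole coordinate range.
#'
#' @param x An [analysis_matrix()], [labeled_ts()] or numeric matrix.
#' @param params A [mapper_params()].
#' @param embedding Optionally a precomputed `mapper_embedding` (so a sweep
#'   over cover parameters can reuse one lens).
#' @return A `mapper_graph` carrying `params` and per-node member indices.
#' @examples
#' m <- matrix(rnorm(200), 100, 2)
#' g <- run_mapper(m, mapper_params(4, 40, 2))
#' g
#' @export
run_mapper <- function(x, params, embedding = NULL) {
  stopifnot(inherits(params, "mapper_params"))
  mat <- extract_matrix(x)
  embedding <- embedding %||% compute_filter(mat, params)
  stopifnot(nrow(embedding$coords) == nrow(mat))

  cover <- build_cover(embedding, params$n_intervals, params$overlap_pct)
  clusters <- list(); bins <- integer()
  for (b in seq_len(nrow(cover))) {
    mem <- cover$members[[b]]
    if (!length(mem)) next
    parts <- cluster_bin(mat[mem, , drop = FALSE], params$n_clusters)
    clusters <- c(clusters, purrr::map(parts, function(p) mem[p]))
    bins <- c(bins, rep(cover$bin[b], length(parts)))
  }
  out <- build_nerve(clusters, params = params, bin_ids = bins,
                     n_points = nrow(mat))
  out$embedding <- embedding
  out
}
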