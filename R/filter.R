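#' Mapper parameter triple
#'
#' The three tunables swept in the analysis: the number of cover intervals
#' per filter dimension, the percentage by which consecutive intervals
#' overlap, and the number of single-linkage clusters cut per bin; plus the
#' 2D filter (lens) used to place time points before binning.  The metric is
#' Euclidean throughout.
#'
#' @param n_intervals Intervals per filter dimension (>= 1).
#' @param overlap_pct Overlap percentage between consecutive intervals,
#'   strictly between 0 and 100.
#' @param n_clusters Number of clusters to cut per bin (>= 1); bins smaller
#'   than this yield one cluster per point.
#' @param filter_method `"pca"` (deterministic) or `"tsne"` (reproducible
#'   for a fixed `filter_seed`).
#' @param filter_seed Integer seed for the stochastic filter.
#' @param perplexity t-SNE perplexity; reduced automatically when the data
#'   are too small to support it.
#' @param max_iter t-SNE gradient-descent iterations.
#' @return An object of class `mapper_params`.
#' @examples
#' mapper_params(10, 40, 5)
#' @export
mapper_params <- function(n_intervals, overlap_pct, n_clusters,
                          filter_method = c("pca", "tsne"),
                          filter_seed = 1L, perplexity = 30,
                          max_iter = 500L) {
  filter_method <- match.arg(filter_method)
  if (!is.numeric(n_intervals) || n_intervals < 1 ||
      n_intervals != floor(n_intervals)) {
    abort("`n_intervals` must be a positive integer.")
  }
  if (!is.numeric(overlap_pct) || overlap_pct <= 0 || overlap_pct >= 100) {
    abort("`overlap_pct` must lie strictly between 0 and 100.")
  }
  if (!is.numeric(n_clusters) || n_clusters < 1 ||
      n_clusters != floor(n_clusters)) {
    abort("`n_clusters` must be a positive integer.")
  }
  structure(
    list(n_intervals = as.integer(n_intervals),
         overlap_pct = as.numeric(overlap_pct),
         n_clusters = as.integer(n_clusters),
         filter_method = filter_method,
         filter_seed = as.integer(filter_seed),
         perplexity = as.numeric(perplexity),
         max_iter = as.integer(max_iter),
         metric = "euclidean"),
    class = "mapper_params"
  )
}

#' @export
print.mapper_params <- function(x, ...) {
  cat(sprintf("<mapper_params> %d intervals, %g%% overlap, %d clusters; filter %s (seed %d)\n",
              x$n_intervals, x$overlap_pct, x$n_clusters, x$filter_method,
              x$filter_seed))
  invisible(x)
}

#' Compute the 2D filter (lens) of an analysis matrix
#'
#' Maps every time point to two dimensions: either the first two principal
#' components (deterministic, preserves pairwise Euclidean distances exactly
#' on rank-2 data) or a t-SNE embedding, which preserves local neighbourhood
#' structure of the Euclidean similarity and is reproducible for a fixed
#' seed.
#'
#' @param x An [analysis_matrix()], [labeled_ts()] or numeric matrix.
#' @param params A [mapper_params()] carrying the filter choice and seed.
#' @return An object of class `mapper_embedding`: list with `coords`
#'   (n x 2 matrix), `method` and `seed`.
#' @examples
#' m <- matrix(rnorm(60), 20, 3)
#' emb <- compute_filter(m, mapper_params(4, 30, 2))
#' dim(emb$coords)
#' @export
compute_filter <- function(x, params) {
  stopifnot(inherits(params, "mapper_params"))
  mat <- extract_matrix(x)
  if (!nrow(mat)) abort("input matrix is empty.", class = "data_error")
  if (!all(is.finite(mat))) {
    abort("input matrix contains non-finite values.", class = "data_error")
  }
  coords <- switch(
    params$filter_method,
    pca = pca_lens(mat),
    tsne = {
      if (nrow(mat) < 3) abort("t-SNE needs at least 3 rows.", class = "data_error")
      tsne_lens(mat, perplexity = params$perplexity,
                max_iter = params$max_iter, seed = params$filter_seed)
    })
  structure(list(coords = coords, method = params$filter_method,
                 seed = params$filter_seed),
            class = "mapper_embedding")
}

extract_matrix <- function(x) {
  if (inherits(x, "analysis_matrix") || inherits(x, "labeled_ts")) return(x$data)
  if (is.matrix(x) && is.numeric(x)) return(x)
  abort("`x` must be an analysis_matrix, labeled_ts or numeric matrix.")
}

pca_lens <- function(mat) {
  pc <- prcomp(mat, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  coords <- matrix(0, nrow(mat), 2)
  if (k > 0) coords[, seq_len(k)] <- pc$x[, seq_len(k), drop = FALSE]
  colnames(coords) <- c("dim1", "dim2")
  coords
}

# Exact (O(n^2)) t-SNE to two dimensions.  Perplexity-calibrated Gaussian
# affinities with a per-point bisection on the bandwidth, symmetrised and
# early-exaggerated; gradient descent with momentum on the Student-t
# low-dimensional kernel.  Deterministic for a fixed seed.
tsne_lens <- function(mat, perplexity = 30, max_iter = 500, seed = 1L) {
  n <- nrow(mat)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  perplexity <- max(perplexity, 2)
  d2 <- as.matrix(dist(mat))^2

  P <- matrix(0, n, n)
  log_u <- log(perplexity)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta <- 1; beta_min <- -Inf; beta_max <- Inf
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < .Machine$double.xmin) { h <- 0 } else {
        h <- log(sw) + beta * sum(di * w) / sw
      }
      if (abs(h - log_u) < 1e-5) break
      if (h > log_u) {
        beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else {
        beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    w <- exp(-di * beta)
    P[i, -i] <- w / max(sum(w), .Machine$double.xmin)
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12

  Y <- withr::with_seed(seed, matrix(rnorm(n * 2, sd = 1e-4), n, 2))
  gains <- matrix(1, n, 2); inc <- matrix(0, n, 2)
  eta <- 200; exaggeration <- 12
  P_run <- P * exaggeration
  for (iter in seq_len(max_iter)) {
    if (iter == 101) P_run <- P
    momentum <- if (iter < 251) 0.5 else 0.8
    sum_y2 <- rowSums(Y^2)
    num <- 1 / (1 + outer(sum_y2, sum_y2, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q[Q < 1e-12] <- 1e-12
    L <- (P_run - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    inc <- momentum * inc - eta * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  colnames(Y) <- c("dim1", "dim2")
  Y
}

#' @export
print.mapper_embedding <- function(x, ...) {
  cat(sprintf("<mapper_embedding> %d points, method %s (seed %d)\n",
              nrow(x$coords), x$method, x$seed))
  invisible(x)
}
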