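test_that("interval geometry follows the closed form L = R / (n - (n-1)o)", {
  # range [0, 3], n = 2, o = 0.5 -> L = 2, intervals [0,2] and [1,3]
  emb <- structure(list(coords = cbind(c(0, 1, 2, 3), c(0, 1, 2, 3))),
                   class = "mapper_embedding")
  cov <- build_cover(emb, 2, 50)
  iv <- attr(cov, "intervals")$x
  expect_equal(iv$start, c(0, 1))
  expect_equal(iv$end, c(2, 3))
})

test_that("one interval gives one bin equal to the bounding box", {
  emb <- structure(list(coords = cbind(runif(20), runif(20))),
                   class = "mapper_embedding")
  cov <- build_cover(emb, 1, 30)
  expect_equal(nrow(cov), 1)
  expect_equal(cov$xmin, min(emb$coords[, 1]))
  expect_equal(cov$xmax, max(emb$coords[, 1]))
  expect_equal(length(cov$members[[1]]), 20)
})

test_that("the bounding-box center belongs to all four bins at n = 2", {
  pts <- cbind(c(0, 1, 0.5), c(0, 1, 0.5))  # corners set the range
  emb <- structure(list(coords = pts), class = "mapper_embedding")
  cov <- build_cover(emb, 2, 50)
  in_bins <- vapply(cov$members, function(m) 3 %in% m, logical(1))
  expect_equal(sum(in_bins), 4)
})

test_that("cover algebra holds for every triple of the study grid", {
  emb <- structure(list(coords = withr::with_seed(1, cbind(rnorm(150), rnorm(150)))),
                   class = "mapper_embedding")
  grid <- enumerate_grid(sweep_spec())
  for (r in seq_len(nrow(grid))) {
    n <- grid$n_intervals[r]; o <- grid$overlap_pct[r] / 100
    cov <- build_cover(emb, n, grid$overlap_pct[r])
    for (dim_iv in attr(cov, "intervals")) {
      L <- dim_iv$end[1] - dim_iv$start[1]
      R <- max(dim_iv$end) - min(dim_iv$start)
      expect_equal(L * (n - (n - 1) * o), R, tolerance = 1e-12)
      # union of intervals covers the range with no gap
      expect_true(all(dim_iv$start[-1] <= dim_iv$end[-n] + 1e-12))
    }
    counts <- table(factor(unlist(cov$members), levels = 1:150))
    expect_true(all(counts >= 1))
    if (o < 0.5) expect_true(all(counts <= 4))
  }
})

test_that("degenerate coordinate ranges collapse to one interval with a warning", {
  emb <- structure(list(coords = cbind(runif(10), rep(2, 10))),
                   class = "mapper_embedding")
  expect_warning(cov <- build_cover(emb, 3, 40), "degenerate")
  expect_equal(nrow(cov), 3)  # 3 x-intervals x 1 collapsed y-interval
})

test_that("single-linkage bin clustering matches the exhaustive merge order", {
  expect_equal(cluster_bin(matrix(1.5), 3), list(1L))
  # 1D rows {0, 1, 10, 11}: first merges are 0-1 and 10-11, so the 2-cut
  # must be {1,2} and {3,4}
  parts <- cluster_bin(matrix(c(0, 1, 10, 11)), 2)
  expect_setequal(lapply(parts, sort), list(c(1L, 2L), c(3L, 4L)))
  # cutting above the leaves yields all singletons
  parts2 <- cluster_bin(matrix(c(0, 1, 10, 11)), 10)
  expect_equal(sort(lengths(parts2)), rep(1L, 4))
  # clusters always partition the bin
  x <- withr::with_seed(2, matrix(rnorm(30), 15, 2))
  parts3 <- cluster_bin(x, 4)
  expect_setequal(unlist(parts3), 1:15)
})

test_that("nerve edges are exactly the nonempty pairwise intersections", {
  g0 <- build_nerve(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(igraph::ecount(g0$graph), 0)

  g1 <- build_nerve(list(c(1, 2), c(2, 3), 4))
  expect_equal(edge_set(g1$graph), matrix(c(1L, 2L), 1))

  g2 <- build_nerve(list(c(7, 1), c(7, 2), c(7, 3)))
  expect_equal(igraph::ecount(g2$graph), 3)

  # randomized oracle check
  for (s in 1:5) {
    clusters <- withr::with_seed(s, {
      k <- sample(5:60, 1)
      lapply(seq_len(k), function(i) sample(1:80, sample(1:6, 1)))
    })
    g <- build_nerve(clusters)
    expect_equal(edge_set(g$graph), unname(brute_force_edges(clusters)))
  }
})

test_that("PCA lens is exact on rank-2 data and degenerate on constants", {
  const <- matrix(5, 10, 3)
  emb <- compute_filter(const, mapper_params(2, 30, 1))
  expect_true(all(emb$coords == 0))

  basis <- withr::with_seed(3, matrix(rnorm(8), 2, 4))
  loads <- withr::with_seed(4, matrix(rnorm(40), 20, 2))
  rank2 <- loads %*% basis
  emb2 <- compute_filter(rank2, mapper_params(2, 30, 1))
  expect_equal(as.matrix(dist(emb2$coords)), as.matrix(dist(rank2)),
               tolerance = 1e-8)
})

test_that("t-SNE lens is reproducible for a fixed seed", {
  x <- withr::with_seed(5, rbind(matrix(rnorm(40, 0), 20, 2),
                                 matrix(rnorm(40, 6), 20, 2)))
  p <- mapper_params(3, 40, 2, filter_method = "tsne", filter_seed = 7,
                     max_iter = 150)
  e1 <- compute_filter(x, p)
  e2 <- compute_filter(x, p)
  expect_identical(e1$coords, e2$coords)
  # the two well-separated groups stay separated in the embedding
  d <- as.matrix(dist(e1$coords))
  within <- mean(d[1:20, 1:20])
  between <- mean(d[1:20, 21:40])
  expect_gt(between, within)
  expect_error(compute_filter(x[1:2, ], p), class = "data_error")
})

test_that("non-finite input is rejected by the filter", {
  x <- matrix(rnorm(30), 10, 3); x[2, 2] <- NaN
  expect_error(compute_filter(x, mapper_params(2, 30, 1)),
               class = "data_error")
})

test_that("the full construction is deterministic and conserves membership", {
  x <- withr::with_seed(6, rbind(matrix(rnorm(120, 0), 60, 2),
                                 matrix(rnorm(120, 8), 60, 2)))
  p <- mapper_params(4, 40, 2)
  g1 <- run_mapper(x, p)
  g2 <- run_mapper(x, p)
  expect_identical(g1$nodes$members, g2$nodes$members)
  expect_identical(edge_set(g1$graph), edge_set(g2$graph))
  # no time point lost
  expect_setequal(unlist(g1$nodes$members), seq_len(nrow(x)))
  # two well-separated blobs: either >= 2 components or a sparse bridge
  comp <- igraph::components(g1$graph)
  expect_true(comp$no >= 2 ||
                igraph::ecount(g1$graph) < igraph::vcount(g1$graph)^2 / 4)
})

test_that("the degenerate cover yields a single all-member node", {
  x <- withr::with_seed(7, matrix(rnorm(40), 20, 2))
  g <- run_mapper(x, mapper_params(1, 50, 1))
  expect_equal(igraph::vcount(g$graph), 1)
  expect_equal(igraph::ecount(g$graph), 0)
  expect_equal(sort(g$nodes$members[[1]]), 1:20)
})

test_that("node count never decreases as intervals increase on a fixed lens", {
  x <- withr::with_seed(8, matrix(rnorm(400), 200, 2))
  p0 <- mapper_params(2, 40, 3)
  emb <- compute_filter(x, p0)
  counts <- vapply(c(2, 4, 6, 10), function(ni) {
    igraph::vcount(run_mapper(x, mapper_params(ni, 40, 3), embedding = emb)$graph)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
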