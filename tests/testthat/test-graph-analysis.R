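test_that("node dominance takes the strict majority and flags exact ties", {
  g <- build_nerve(list(c(1, 2, 3), c(4, 5)))
  dom <- label_nodes(g, c("S", "S", "M", "S", "M"))
  expect_equal(dom$label, c("S", "TIE"))
  expect_equal(dom$fraction, c(2 / 3, 0.5))
  # conservation: counts over labels sum to the node count
  expect_equal(sum(table(dom$label)), nrow(g$nodes))
  expect_error(label_nodes(g, c("S", "S")), class = "data_error")
})

test_that("centrality closed forms match on path, star and complete graphs", {
  path3 <- build_nerve(list(c(1), c(1, 2), c(2)))  # 1 - 2 - 3 path
  btw <- node_centrality(path3, "betweenness")
  expect_equal(btw$score, c(0, 1, 0))

  star <- build_nerve(list(c(1, 2, 3, 4), c(1), c(2), c(3), c(4)))
  clo <- node_centrality(star, "closeness")
  expect_equal(clo$score[1], 1)
  expect_equal(clo$score[2], 4 / 7)

  complete4 <- build_nerve(list(c(1, 2), c(1, 3), c(2, 3), c(1, 4)))
  # all four clusters share points pairwise? build explicitly instead:
  complete4 <- build_nerve(list(c(1, 2, 3), c(1, 4, 5), c(2, 4, 6), c(3, 5, 6)))
  expect_equal(igraph::ecount(complete4$graph), 6)
  expect_equal(node_centrality(complete4, "degree")$score, rep(1, 4))

  expect_error(node_centrality(path3, "pagerank"))
})

test_that("degree centrality is monotone under edge addition and closeness is in (0,1]", {
  for (s in 1:5) {
    g <- withr::with_seed(s, igraph::sample_gnp(12, 0.3))
    if (igraph::count_components(g) > 1) {
      g <- igraph::add_edges(g, rbind(1, 2:12)[, 1:2])  # loosely connect
    }
    g <- igraph::simplify(g)
    if (igraph::count_components(g) > 1) next
    clo <- node_centrality(g, "closeness")
    expect_true(all(clo$score > 0 & clo$score <= 1))
    deg0 <- node_centrality(g, "degree")$score
    if (!igraph::are_adjacent(g, 1, 2)) {
      g2 <- igraph::add_edges(g, c(1, 2))
      deg1 <- node_centrality(g2, "degree")$score
      expect_gte(deg1[1], deg0[1])
      expect_gte(deg1[2], deg0[2])
    }
  }
})

test_that("disconnected graphs are restricted to the largest component", {
  g <- build_nerve(list(c(1, 2), c(2, 3), c(4, 5), c(5, 6), c(6, 7), 8))
  expect_warning(clo <- node_centrality(g, "closeness"), "components")
  expect_equal(clo$node, c(3, 4, 5))  # the 3-node chain is largest
  expect_error(node_centrality(g, "closeness", on_disconnected = "error"),
               class = "disconnected_graph")
})

test_that("paradigm means average dominated nodes only and flag empty paradigms", {
  scores <- tibble::tibble(node = 1:3, score = c(0.2, 0.4, 0.6))
  dom <- tibble::tibble(node = 1:3, label = c("A", "A", "B"),
                        fraction = 1, size = 5)
  out <- paradigm_mean_centrality(scores, dom)
  expect_equal(out$mean_score[out$label == "A"], 0.3)
  expect_equal(out$mean_score[out$label == "B"], 0.6)

  dom_tie <- tibble::tibble(node = 1:3, label = "TIE", fraction = 0.5, size = 2)
  expect_warning(out2 <- paradigm_mean_centrality(scores, dom_tie,
                                                  paradigms = c("A", "B")),
                 "mean undefined")
  expect_true(all(is.na(out2$mean_score)))
  expect_equal(unique(out2$n_tie), 3L)
})

test_that("greedy community detection recovers exhaustive-search partitions", {
  # two disjoint triangles: brute force over all partitions of 6 nodes
  tri2 <- build_nerve(list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
  best_q <- -Inf; best_m <- NULL
  for (p in all_partitions(6)) {
    m <- partition_to_membership(p, 6)
    q <- brute_force_modularity(tri2$graph, m)
    if (q > best_q) { best_q <- q; best_m <- m }
  }
  expect_equal(best_q, 0.5)
  got <- detect_communities(tri2)
  expect_equal(graph_modularity(tri2, got), 0.5)
  # the detected partition separates the triangles
  expect_equal(length(unique(got$community[1:3])), 1)
  expect_equal(length(unique(got$community[4:6])), 1)
  expect_false(got$community[1] == got$community[4])

  # complete graph: exhaustive search says one community is optimal
  k4 <- igraph::make_full_graph(4)
  best_q <- max(vapply(all_partitions(4), function(p) {
    brute_force_modularity(k4, partition_to_membership(p, 4))
  }, numeric(1)))
  expect_equal(best_q, 0)
  got4 <- detect_communities(k4)
  expect_equal(length(unique(got4$community)), 1)
})

test_that("edgeless graphs get singleton communities and Q = 0 by convention", {
  g <- build_nerve(list(1, 2, 3))
  expect_message(cm <- detect_communities(g), "edgeless")
  expect_equal(cm$community, 1:3)
  expect_message(q <- graph_modularity(g, cm), "convention")
  expect_equal(q, 0)
})

test_that("modularity matches its closed forms and the double-sum oracle", {
  tri2 <- build_nerve(list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
  expect_equal(graph_modularity(tri2, rep(1, 6)), 0)        # one community
  expect_equal(graph_modularity(tri2, c(1, 1, 1, 2, 2, 2)), 0.5)
  single_edge <- build_nerve(list(c(1, 9), c(9, 2)))
  expect_equal(graph_modularity(single_edge, c(1, 2)), -0.5)

  for (s in 1:8) {
    g <- withr::with_seed(s, igraph::sample_gnp(sample(3:8, 1), 0.5))
    if (igraph::ecount(g) == 0) next
    m <- withr::with_seed(s + 100,
                          sample(1:3, igraph::vcount(g), replace = TRUE))
    expect_equal(graph_modularity(g, m), brute_force_modularity(g, m),
                 tolerance = 1e-12)
  }
  expect_error(graph_modularity(tri2, c(1, 1, 1)), class = "usage_error")
})
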