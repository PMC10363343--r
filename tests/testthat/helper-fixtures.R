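# Small deterministic builders shared across test files.

# labeled_ts with explicit values; channels default c("c1", "c2", ...)
make_ts <- function(data, paradigm = "wm", phase = "stimulus", rate = 256,
                    subject = "s01", channels = NULL) {
  if (!is.matrix(data)) data <- matrix(data, ncol = 1)
  labeled_ts(data, channels = channels, sampling_rate = rate,
             paradigm = paradigm, phase = phase, subject = subject)
}

# a small two-paradigm cohort under the canonical study conditions
small_cohort <- function(n_subjects = 4, seed = 1, nt = 80, nch = 6) {
  cfg <- study_configs(n_channels = nch, n_timepoints = nt)
  generate_cohort(n_subjects, cfg$demanding, cfg$relaxed, seed = seed)
}

# brute-force nerve: all-pairs intersection test
brute_force_edges <- function(clusters) {
  k <- length(clusters)
  out <- matrix(integer(), ncol = 2)
  if (k < 2) return(out)
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      if (length(intersect(clusters[[i]], clusters[[j]]))) {
        out <- rbind(out, c(i, j))
      }
    }
  }
  out
}

# canonical sorted integer edge list of an igraph object
edge_set <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  if (!nrow(el)) return(matrix(integer(), ncol = 2))
  el <- matrix(as.integer(t(apply(el, 1, sort))), ncol = 2)
  el[order(el[, 1], el[, 2]), , drop = FALSE]
}

# Newman modularity by the literal double sum over ordered node pairs
brute_force_modularity <- function(g, membership) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  k <- rowSums(A)
  m2 <- sum(k)  # 2m
  if (m2 == 0) return(0)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + A[i, j] - k[i] * k[j] / m2
      }
    }
  }
  unname(q / m2)
}

# all set partitions of seq_len(n) (Bell-number enumeration, small n only)
all_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  smaller <- all_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    for (b in seq_along(p)) {
      q <- p; q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(p, list(n))
  }
  out
}

partition_to_membership <- function(p, n) {
  m <- integer(n)
  for (b in seq_along(p)) m[p[[b]]] <- b
  m
}
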