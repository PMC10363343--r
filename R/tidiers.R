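#' Tidy a paired test result
#'
#' @param x A `paired_test` from [paired_t_test()] or
#'   [paired_permutation_test()].
#' @param ... Unused.
#' @return A one-row tibble with the test type, observed mean difference,
#'   tail probabilities, p-value, alternative and pair count.
#' @export
tidy.paired_test <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, t = x$t,
         p_l = x$p_l, p_g = x$p_g, p_value = x$p_value,
         alternative = x$alternative, n_pairs = x$n_pairs,
         n_perm = as.character(x$n_perm))
}

#' Tidy a hypothesis comparison
#'
#' @param x A `hypothesis_result` from [compare_paradigms()].
#' @param ... Unused.
#' @return The per-(triple, measure) comparison table as a tibble.
#' @export
tidy.hypothesis_result <- function(x, ...) as_tibble(x$table)

#' One-row summary of a hypothesis comparison
#'
#' @param x A `hypothesis_result`.
#' @param ... Unused.
#' @return A one-row tibble: paradigms, satisfied flag, satisfying
#'   fraction, family size and significance level.
#' @export
glance.hypothesis_result <- function(x, ...) {
  tibble(paradigm_a = x$paradigm_a, paradigm_b = x$paradigm_b,
         satisfied = x$satisfied, fraction = x$fraction,
         n_comparisons = nrow(x$table), m = x$m, alpha = x$alpha)
}

#' One-row summary of a Mapper graph
#'
#' @param x A `mapper_graph`.
#' @param ... Unused.
#' @return A one-row tibble: node count, edge count, connectivity flag,
#'   number of time points and the parameter triple.
#' @export
glance.mapper_graph <- function(x, ...) {
  tibble(n_nodes = igraph::vcount(x$graph),
         n_edges = igraph::ecount(x$graph),
         connected = igraph::count_components(x$graph) == 1,
         n_points = x$n_points,
         n_intervals = x$params$n_intervals %||% NA_integer_,
         overlap_pct = x$params$overlap_pct %||% NA_real_,
         n_clusters = x$params$n_clusters %||% NA_integer_)
}
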