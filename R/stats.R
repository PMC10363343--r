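#' Paired per-subject scores for two conditions
#'
#' The object the paired tests consume: one row per subject with the two
#' conditions' scores in a fixed order.
#'
#' @param subject Character vector of subject ids.
#' @param score_a,score_b Numeric score vectors, same length as `subject`.
#' @param labels Length-2 character vector naming the two conditions.
#' @return A tibble of class `paired_sample` with columns `subject`,
#'   `score_a`, `score_b` and attribute `labels`.
#' @examples
#' paired_sample(c("s1", "s2"), c(0.3, 0.4), c(0.2, 0.35))
#' @export
paired_sample <- function(subject, score_a, score_b,
                          labels = c("A", "B")) {
  subject <- as.character(subject)
  if (length(subject) < 2 || length(score_a) != length(subject) ||
      length(score_b) != length(subject)) {
    abort("`subject`, `score_a` and `score_b` must have equal length >= 2.")
  }
  stopifnot(is.numeric(score_a), is.numeric(score_b), length(labels) == 2)
  out <- tibble(subject = subject, score_a = as.numeric(score_a),
                score_b = as.numeric(score_b))
  class(out) <- c("paired_sample", class(out))
  attr(out, "labels") <- as.character(labels)
  out
}

#' Per-subject paired differences
#'
#' @param sample A [paired_sample()].
#' @return Numeric vector `score_a - score_b`, subject order preserved.
#' @examples
#' paired_differences(paired_sample(c("s1", "s2"), c(0.3, 0.4), c(0.2, 0.35)))
#' @export
paired_differences <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  sample$score_a - sample$score_b
}

#' Choose between the paired t-test and the permutation test
#'
#' Applies the Shapiro-Wilk normality test to the vector of paired
#' differences (the quantity whose normality the paired t-test assumes).
#' When normality is rejected at `alpha` the nonparametric sign-flip
#' permutation test is chosen; otherwise the paired t-test.  Constant
#' differences leave normality undefined: the permutation test is chosen
#' with a warning.
#'
#' @param differences Numeric vector of paired differences (length >= 3).
#' @param alpha Significance level of the normality gate.
#' @return A list with `test` (`"paired_t"` or `"paired_permutation"`) and
#'   `normality_p` (NA when undefined).
#' @examples
#' normality_gate(rnorm(30))
#' @export
normality_gate <- function(differences, alpha = 0.05) {
  if (length(differences) < 3) abort("need at least 3 differences.")
  if (length(unique(differences)) == 1) {
    warn("constant differences: normality undefined, choosing the permutation test.")
    return(list(test = "paired_permutation", normality_p = NA_real_))
  }
  p <- shapiro.test(differences)$p.value
  list(test = if (p < alpha) "paired_permutation" else "paired_t",
       normality_p = p)
}

#' Classical paired t-test
#'
#' @param sample A [paired_sample()].
#' @param alternative `"two_sided"`, `"greater"` or `"less"` (first score
#'   minus second).
#' @return A `paired_test` object: list with `statistic` (observed mean
#'   difference), `t`, `p_value`, `alternative`, `n_pairs`, `test`.
#' @examples
#' s <- paired_sample(paste0("s", 1:3), c(2, 3, 4), c(1, 1, 1))
#' paired_t_test(s)$p_value
#' @export
paired_t_test <- function(sample,
                          alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  d <- paired_differences(sample)
  if (length(unique(d)) == 1) {
    abort("differences are constant: t statistic undefined.",
          class = "undefined_variance")
  }
  alt <- c(two_sided = "two.sided", greater = "greater", less = "less")[alternative]
  tt <- t.test(sample$score_a, sample$score_b, paired = TRUE,
               alternative = alt)
  structure(
    list(test = "paired_t", statistic = mean(d),
         t = unname(tt$statistic), p_value = tt$p.value,
         p_l = NA_real_, p_g = NA_real_,
         alternative = alternative, n_pairs = length(d),
         n_perm = NA_integer_, labels = attr(sample, "labels")),
    class = c("paired_t", "paired_test"))
}

#' Paired sign-flip permutation test
#'
#' Test statistic: the mean of the per-subject differences.  Under the null
#' of exchangeable conditions, each subject's pair may be swapped, i.e. its
#' difference sign-flipped; the null distribution is the statistic over
#' sign-flip patterns.  With `mode = "exact"` (the default for
#' `n <= max_exact` pairs) all `2^n` patterns are enumerated; otherwise
#' `n_perm` patterns are drawn with the given seed and tail probabilities
#' are add-one smoothed (`(count + 1) / (n_perm + 1)`), so a p-value of
#' exactly zero cannot occur.  Tails are inclusive:
#' `p_g = P(statistic >= mu_obs)`, `p_l = P(statistic <= mu_obs)`; the
#' two-sided p-value is `min(1, 2 * min(p_l, p_g))` and a one-sided
#' alternative uses the corresponding tail.
#'
#' @param sample A [paired_sample()].
#' @param alternative `"two_sided"`, `"greater"` or `"less"`.
#' @param n_perm Number of Monte Carlo sign patterns (ignored in exact
#'   mode).
#' @param seed Integer seed for the Monte Carlo draw.
#' @param mode `"auto"` (exact when feasible), `"exact"` or
#'   `"monte_carlo"`.
#' @param max_exact Largest number of pairs enumerated exhaustively.
#' @return A `paired_test` object with `statistic` (`mu_obs`), `p_l`,
#'   `p_g`, `p_value`, `n_perm` (`"exact"` or the Monte Carlo count).
#' @examples
#' s <- paired_sample(paste0("s", 1:3), c(2, 3, 4), c(1, 1, 1))
#' paired_permutation_test(s)$p_value  # d = {1,2,3}: two-sided p = 0.25
#' @export
paired_permutation_test <- function(sample,
                                    alternative = c("two_sided", "greater", "less"),
                                    n_perm = 10000L, seed = 1L,
                                    mode = c("auto", "exact", "monte_carlo"),
                                    max_exact = 20L) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  d <- paired_differences(sample)
  n <- length(d)
  if (mode == "auto") mode <- if (n <= max_exact) "exact" else "monte_carlo"
  if (mode == "exact" && n > max_exact) {
    abort(sprintf("exact enumeration limited to %d pairs.", max_exact),
          class = "usage_error")
  }
  if (mode == "monte_carlo" && (!is.numeric(n_perm) || n_perm < 1)) {
    abort("`n_perm` must be >= 1.", class = "usage_error")
  }
  mu_obs <- mean(d)
  tol <- 1e-12 * max(1, abs(mu_obs))

  if (mode == "exact") {
    stats_null <- exact_signflip_stats(d)
    p_g <- mean(stats_null >= mu_obs - tol)
    p_l <- mean(stats_null <= mu_obs + tol)
    n_perm_used <- "exact"
  } else {
    n_perm <- as.integer(n_perm)
    stats_null <- withr::with_seed(as.integer(seed), {
      signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                      nrow = n_perm, ncol = n)
      as.numeric(signs %*% d) / n
    })
    p_g <- (sum(stats_null >= mu_obs - tol) + 1) / (n_perm + 1)
    p_l <- (sum(stats_null <= mu_obs + tol) + 1) / (n_perm + 1)
    n_perm_used <- n_perm
  }
  p <- switch(alternative,
              two_sided = min(1, 2 * min(p_l, p_g)),
              greater = p_g,
              less = p_l)
  structure(
    list(test = "paired_permutation", statistic = mu_obs,
         t = NA_real_, p_value = p, p_l = p_l, p_g = p_g,
         alternative = alternative, n_pairs = n, n_perm = n_perm_used,
         labels = attr(sample, "labels")),
    class = c("paired_permutation", "paired_test"))
}

# All 2^n sign-flip statistics by meet-in-the-middle: signed subset sums of
# the two halves combined by outer addition, then divided by n.
exact_signflip_stats <- function(d) {
  n <- length(d)
  h <- n %/% 2
  s1 <- signed_sums(d[seq_len(h)])
  s2 <- signed_sums(d[setdiff(seq_len(n), seq_len(h))])
  as.vector(outer(s1, s2, "+")) / n
}

signed_sums <- function(d) {
  s <- 0
  for (di in d) s <- c(s + di, s - di)
  s
}

#' @export
print.paired_test <- function(x, ...) {
  lab <- if (!is.null(x$labels)) paste(x$labels, collapse = " vs ") else "A vs B"
  cat(sprintf("<%s> %s: mean difference %.4g, %s p = %.4g (n = %d pairs",
              x$test, lab, x$statistic, x$alternative, x$p_value, x$n_pairs))
  if (identical(x$test, "paired_permutation")) {
    cat(sprintf(", permutations = %s", as.character(x$n_perm)))
  }
  cat(")\n")
  invisible(x)
}

#' Bonferroni correction
#'
#' @param raw_p Raw p-value(s) in `[0, 1]`.
#' @param m Family size (>= 1).
#' @return `min(1, m * raw_p)`, vectorized over `raw_p`.
#' @examples
#' bonferroni(0.01, 5)
#' @export
bonferroni <- function(raw_p, m) {
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m != floor(m)) {
    abort("`m` must be a positive integer.")
  }
  if (any(raw_p < 0 | raw_p > 1, na.rm = TRUE)) {
    abort("`raw_p` must lie in [0, 1].")
  }
  pmin(1, m * raw_p)
}

#' Correlate two score vectors
#'
#' Pearson (default) or Spearman correlation with a two-sided significance
#' p-value, e.g. between per-subject modularity and response time.
#'
#' @param x,y Equal-length numeric vectors (length >= 3, non-constant).
#' @param method `"pearson"` or `"spearman"`.
#' @return A tibble `estimate`, `p_value`, `method`, `n`.
#' @examples
#' correlate_scores(1:4, c(2, 1, 4, 3))  # Pearson r = 0.6
#' @export
correlate_scores <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must have equal length >= 3.")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined for constant input.",
          class = "undefined_correlation")
  }
  ct <- cor.test(x, y, method = method, exact = FALSE)
  tibble(estimate = unname(ct$estimate), p_value = ct$p.value,
         method = method, n = length(x))
}

#' Compare two paradigms across subjects (and a parameter sweep)
#'
#' The full inference route of the pipeline for one directed hypothesis, e.g.
#' "mean node centrality under the demanding paradigm exceeds the relaxed
#' one": for every parameter triple (and centrality measure) present in
#' `summaries`, the per-subject paradigm means are paired, the
#' Shapiro-Wilk gate selects the paired t-test or the sign-flip permutation
#' test (two-sided, as the null states equality), the p-value is Bonferroni
#' corrected with family size `m`, and the direction is read off the sample
#' means.  The hypothesis is *satisfied* when the corrected p-value is
#' below `alpha` **and** the sample-mean ordering matches, in at least
#' `satisfied_frac` of the rows.
#'
#' @param summaries Tibble of per-subject paradigm means as produced by
#'   [run_sweep()] (columns `subject`, `label`, `mean_score`, plus optional
#'   grouping columns `n_intervals`, `overlap_pct`, `n_clusters`,
#'   `measure`).
#' @param paradigm_a,paradigm_b The two paradigm labels; the hypothesis is
#'   that `paradigm_a`'s mean exceeds `paradigm_b`'s.
#' @param alpha Significance level.
#' @param m Bonferroni family size; default is the number of parameter
#'   triples present per comparison family.
#' @param satisfied_frac Fraction of rows that must individually satisfy the
#'   directed, corrected-significant outcome.
#' @param n_perm,seed Monte Carlo settings passed to the permutation test.
#' @return A `hypothesis_result`: list with the per-row `table`, the
#'   overall `satisfied` flag, `fraction` of satisfying rows, and the
#'   configuration.
#' @export
compare_paradigms <- function(summaries, paradigm_a, paradigm_b,
                              alpha = 0.05, m = NULL,
                              satisfied_frac = 0.95,
                              n_perm = 10000L, seed = 1L) {
  needed <- c("subject", "label", "mean_score")
  if (!all(needed %in% names(summaries))) {
    abort("`summaries` must have columns subject, label, mean_score.")
  }
  group_cols <- intersect(c("n_intervals", "overlap_pct", "n_clusters",
                            "measure"), names(summaries))
  triple_cols <- intersect(c("n_intervals", "overlap_pct", "n_clusters"),
                           group_cols)
  wide <- summaries |>
    filter(.data$label %in% c(paradigm_a, paradigm_b)) |>
    select(dplyr::all_of(c("subject", group_cols, "label", "mean_score"))) |>
    tidyr::pivot_wider(names_from = "label", values_from = "mean_score")
  if (!all(c(paradigm_a, paradigm_b) %in% names(wide))) {
    abort("both paradigms must appear in `summaries`.")
  }
  m_default <- if (length(triple_cols)) {
    nrow(dplyr::distinct(wide[triple_cols]))
  } else 1L
  m <- m %||% m_default

  groups <- if (length(group_cols)) {
    dplyr::group_split(dplyr::group_by(wide, dplyr::across(dplyr::all_of(group_cols))))
  } else list(wide)
  rows <- purrr::map(groups, function(gdf) {
    key <- gdf[1, group_cols, drop = FALSE]
    complete <- gdf[stats::complete.cases(gdf[[paradigm_a]], gdf[[paradigm_b]]), ]
    if (nrow(complete) < 2) {
      abort("fewer than 2 subjects with both paradigm means defined.",
            class = "insufficient_data")
    }
    ps <- paired_sample(complete$subject, complete[[paradigm_a]],
                        complete[[paradigm_b]],
                        labels = c(paradigm_a, paradigm_b))
    d <- paired_differences(ps)
    gate <- normality_gate(d, alpha = alpha)
    res <- if (gate$test == "paired_t") {
      paired_t_test(ps, alternative = "two_sided")
    } else {
      paired_permutation_test(ps, alternative = "two_sided",
                              n_perm = n_perm, seed = seed)
    }
    corrected <- bonferroni(res$p_value, m)
    dplyr::bind_cols(key, tibble(
      n_subjects = nrow(complete),
      test = res$test, normality_p = gate$normality_p,
      statistic = res$statistic, raw_p = res$p_value,
      corrected_p = corrected,
      direction_ok = res$statistic > 0,
      satisfied = corrected < alpha && res$statistic > 0))
  })
  table <- bind_rows(rows)
  fraction <- mean(table$satisfied)
  structure(
    list(table = table, satisfied = fraction >= satisfied_frac,
         fraction = fraction, paradigm_a = paradigm_a,
         paradigm_b = paradigm_b, alpha = alpha, m = m,
         satisfied_frac = satisfied_frac),
    class = "hypothesis_result")
}

#' @export
print.hypothesis_result <- function(x, ...) {
  cat(sprintf("<hypothesis_result> %s > %s: %s (%.0f%% of %d comparisons satisfied)\n",
              x$paradigm_a, x$paradigm_b,
              if (x$satisfied) "Satisfied" else "Not Satisfied",
              100 * x$fraction, nrow(x$table)))
  invisible(x)
}
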