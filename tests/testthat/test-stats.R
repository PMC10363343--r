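test_that("paired differences preserve order and match the printed example", {
  tab <- load_table1_fixture()
  d <- paired_differences(tab)
  expect_equal(d[1], 0.2563 - 0.2006)  # 0.0557
  expect_equal(round(mean(d), 4), 0.0547)
  eq <- paired_sample(c("a", "b"), c(1, 2), c(1, 2))
  expect_equal(paired_differences(eq), c(0, 0))
})

test_that("the normality gate routes the printed example to the permutation test", {
  tab <- load_table1_fixture()
  gate <- normality_gate(paired_differences(tab))
  expect_equal(gate$test, "paired_permutation")
  expect_equal(round(gate$normality_p, 2), 0.02)
})

test_that("the gate agrees with the reference normality decision on seeded draws", {
  chose_t <- logical(100)
  for (s in 1:100) {
    d <- withr::with_seed(s, rnorm(500))
    gate <- normality_gate(d)
    ref <- shapiro.test(d)$p.value >= 0.05
    expect_equal(gate$test == "paired_t", ref)
    chose_t[s] <- gate$test == "paired_t"
  }
  expect_gte(mean(chose_t), 0.9)  # standard-normal draws look normal
})

test_that("constant differences fall back to the permutation test with a warning", {
  expect_warning(gate <- normality_gate(rep(0.3, 10)), "constant")
  expect_equal(gate$test, "paired_permutation")
  expect_true(is.na(gate$normality_p))
})

test_that("the paired t-test matches the direct t formula", {
  s <- paired_sample(paste0("s", 1:3), c(2, 3, 4), c(1, 1, 1))  # d = 1,2,3
  res <- paired_t_test(s)
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(res$p_value, 2 * (1 - pt(2 * sqrt(3), df = 2)),
               tolerance = 1e-10)
  # antisymmetry: swapping the columns negates t, keeps the two-sided p
  sw <- paired_sample(paste0("s", 1:3), c(1, 1, 1), c(2, 3, 4))
  res_sw <- paired_t_test(sw)
  expect_equal(res_sw$t, -res$t)
  expect_equal(res_sw$p_value, res$p_value)
  expect_error(paired_t_test(paired_sample(c("a", "b"), c(1, 2), c(0, 1))),
               class = "undefined_variance")
})

test_that("near-symmetric jitter around zero gives p close to 1", {
  d <- c(1e-3, -1e-3, 1e-3, -1e-3, 1e-3, -1e-3)
  s <- paired_sample(paste0("s", 1:6), d, rep(0, 6))
  expect_gt(paired_t_test(s)$p_value, 0.6)
})

test_that("exact sign-flip enumeration matches the explicit 2^n oracle", {
  # d = {1,2,3}: mu_obs = 2 is the unique maximum of the 8 patterns
  s <- paired_sample(paste0("s", 1:3), c(2, 3, 4), c(1, 1, 1))
  res <- paired_permutation_test(s, mode = "exact")
  expect_equal(res$p_g, 1 / 8)
  expect_equal(res$p_l, 1)
  expect_equal(res$p_value, 0.25)
  expect_equal(res$n_perm, "exact")

  # bit-for-bit agreement with a literal enumeration; dyadic differences
  # make every subset sum exactly representable
  for (s_i in 1:4) {
    d <- withr::with_seed(s_i, round(rnorm(6) * 4) / 4)
    if (all(d == 0)) d[1] <- 0.25
    ps <- paired_sample(paste0("s", 1:6), d, rep(0, 6))
    res <- paired_permutation_test(ps, mode = "exact")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 6)))
    null_stats <- signs %*% d / 6
    expect_identical(res$p_g, mean(null_stats >= mean(d) - 1e-12 * max(1, abs(mean(d)))))
    expect_identical(res$p_l, mean(null_stats <= mean(d) + 1e-12 * max(1, abs(mean(d)))))
  }
})

test_that("degenerate and invalid permutation inputs behave as declared", {
  z <- paired_sample(paste0("s", 1:5), rep(1, 5), rep(1, 5))
  res <- paired_permutation_test(z)
  expect_equal(res$p_l, 1); expect_equal(res$p_g, 1)
  expect_equal(res$p_value, 1)
  expect_error(paired_permutation_test(z, mode = "monte_carlo", n_perm = 0),
               class = "usage_error")
  expect_error(paired_permutation_test(z, mode = "exact", max_exact = 3),
               class = "usage_error")
})

test_that("two-sided permutation p is invariant under a global sign flip", {
  for (s_i in 1:3) {
    d <- withr::with_seed(10 + s_i, rnorm(8))
    a <- paired_permutation_test(
      paired_sample(paste0("s", 1:8), d, rep(0, 8)), mode = "exact")
    b <- paired_permutation_test(
      paired_sample(paste0("s", 1:8), -d, rep(0, 8)), mode = "exact")
    expect_equal(a$p_value, b$p_value)
  }
})

test_that("Monte Carlo p converges to the exact p within 3 standard errors", {
  for (n in c(8, 12)) {
    d <- withr::with_seed(n, rnorm(n, mean = 0.4))
    ps <- paired_sample(paste0("s", 1:n), d, rep(0, n))
    ex <- paired_permutation_test(ps, mode = "exact")
    mc <- paired_permutation_test(ps, mode = "monte_carlo", n_perm = 10000,
                                  seed = 99)
    se <- sqrt(ex$p_value * (1 - ex$p_value) / 10000)
    expect_lt(abs(mc$p_value - ex$p_value), 3 * se + 2 / 10001)
    expect_gt(mc$p_value, 0)  # add-one smoothing forbids zero
  }
})

test_that("the permutation statistic reproduces the printed worked example", {
  tab <- load_table1_fixture()
  expect_equal(round(mean(paired_differences(tab)), 4), 0.0547)
  swapped <- tab
  i <- tab$swapped
  tmp <- swapped$score_a[i]
  swapped$score_a[i] <- swapped$score_b[i]
  swapped$score_b[i] <- tmp
  expect_equal(round(mean(paired_differences(swapped)), 4), 0.0490)
})

test_that("type-I error of the gated pipeline is near the nominal level", {
  rej <- vapply(1:1000, function(s) {
    d <- withr::with_seed(s, rnorm(20))
    ps <- paired_sample(paste0("s", 1:20), d, rep(0, 20))
    gate <- suppressWarnings(normality_gate(paired_differences(ps)))
    res <- if (gate$test == "paired_t") paired_t_test(ps) else
      paired_permutation_test(ps, seed = s)
    res$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("Bonferroni correction caps at one and is monotone in m", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(0.37, 1), 0.37)
  p <- 0.004
  corr <- vapply(1:10, function(m) bonferroni(p, m), numeric(1))
  expect_true(all(diff(corr) >= 0))
  expect_true(all(corr <= 1))
  expect_error(bonferroni(1.2, 2))
})

test_that("correlation matches direct arithmetic and rejects degenerate input", {
  expect_equal(correlate_scores(1:10, -(1:10))$estimate, -1)
  expect_equal(correlate_scores(c(1, 2, 3, 4), c(2, 1, 4, 3))$estimate, 0.6)
  x <- withr::with_seed(1, rnorm(400))
  y <- withr::with_seed(2, rnorm(400))
  expect_lt(abs(correlate_scores(x, y)$estimate), 0.15)
  expect_error(correlate_scores(rep(1, 5), 1:5),
               class = "undefined_correlation")
  sp <- correlate_scores(1:10, (1:10)^3, method = "spearman")
  expect_equal(sp$estimate, 1)
})

test_that("paradigm comparison requires two complete subjects and reads direction", {
  summaries <- tibble::tibble(
    subject = rep(paste0("s", 1:6), each = 2),
    label = rep(c("demanding", "relaxed"), 6),
    mean_score = rep(c(0.5, 0.3), 6) + withr::with_seed(1, rnorm(12, 0, 0.01)))
  hr <- compare_paradigms(summaries, "demanding", "relaxed")
  expect_true(hr$satisfied)
  expect_true(all(hr$table$statistic > 0))
  expect_s3_class(tidy(hr), "tbl_df")
  expect_equal(nrow(glance(hr)), 1)

  # reversed direction: significant but wrong sign -> not satisfied
  hr_rev <- compare_paradigms(summaries, "relaxed", "demanding")
  expect_false(hr_rev$satisfied)

  one <- summaries[1:2, ]
  expect_error(compare_paradigms(one, "demanding", "relaxed"),
               class = "insufficient_data")
})
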