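test_that("signed-rank sums match hand-ranked small cases", {
  w <- wilcoxon_signed_rank(c(1, -2, 3))
  expect_equal(w$w_plus, 4)   # ranks 1, 3 of |1|, |3|
  expect_equal(w$w_minus, 2)  # rank 2 of |-2|
  expect_equal(w$n_used, 3L)
  # antisymmetric differences balance the two sums
  w2 <- wilcoxon_signed_rank(c(1, -1, 2, -2))
  expect_equal(w2$w_plus, w2$w_minus)
})

test_that("rank-sum conservation holds for every input under drop policy", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:40, 1L)
    d <- round(rnorm(n), sample(0:2, 1L)) # induces zeros and ties
    if (all(d == 0)) d[1L] <- 1
    w <- wilcoxon_signed_rank(d, zero_policy = "drop")
    expect_equal(w$w_plus + w$w_minus, w$n_used * (w$n_used + 1) / 2)
  }
})

test_that("exact p-value equals full 2^n sign enumeration for n <= 10", {
  set.seed(19)
  for (rep in 1:10) {
    n <- sample(3:10, 1L)
    d <- rnorm(n) # continuous: tie-free almost surely
    w <- wilcoxon_signed_rank(d, p_mode = "exact")
    expect_equal(w$p_method, "exact")
    expect_equal(w$p_value, enum_signed_rank_p(d))
  }
})

test_that("exact p-value agrees with the reference implementation", {
  set.seed(23)
  for (rep in 1:5) {
    d <- rnorm(sample(6:20, 1L))
    ours <- wilcoxon_signed_rank(d, p_mode = "exact")
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value)
    expect_equal(ours$w_plus, unname(ref$statistic))
  }
})

test_that("normal approximation with ties matches the reference implementation", {
  set.seed(29)
  d <- round(rnorm(60, sd = 2), 1L)
  d <- d[d != 0]
  ours <- wilcoxon_signed_rank(d, p_mode = "normal")
  ref <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("zero policies differ only in the zeros' rank mass", {
  d <- c(0, 0, 1, -2, 3)
  drop <- wilcoxon_signed_rank(d, zero_policy = "drop")
  pratt <- wilcoxon_signed_rank(d, zero_policy = "pratt")
  expect_equal(drop$w_plus, 4); expect_equal(drop$w_minus, 2)
  # pratt ranks zeros (ranks 1.5, 1.5) with the rest, then discards them
  expect_equal(pratt$w_plus, 3 + 5); expect_equal(pratt$w_minus, 4)
  expect_equal(drop$n_used, pratt$n_used)
})

test_that("all-zero differences degenerate to p = 1 with a warning", {
  expect_warning(w <- wilcoxon_signed_rank(c(0, 0, 0)), "degenerate")
  expect_true(w$degenerate)
  expect_equal(w$p_value, 1)
  expect_equal(w$w_plus + w$w_minus, 0)
})

test_that("Bland-Altman of identical raters is all zero", {
  a <- c(1, 2, 3, 4)
  ba <- bland_altman(a, a)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, 0)
  expect_length(ba$outside_indices, 0L)
  expect_error(bland_altman(1, 2), "insufficient data")
})

test_that("Bland-Altman limits are bias -/+ k sd with outside flags", {
  set.seed(31)
  a <- rnorm(50, 10); b <- a + rnorm(50, 0.2, 0.5)
  ba <- bland_altman(a, b, k = 1.96)
  d <- a - b
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$sd, sd(d))
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(ba$outside_indices, which(d < ba$loa_low | d > ba$loa_high))
})

test_that("limits of agreement cover ~95% of Gaussian differences", {
  set.seed(37)
  cover <- vapply(1:1000, function(i) {
    d <- rnorm(30)
    ba <- bland_altman(d, numeric(30))
    1 - length(ba$outside_indices) / 30
  }, numeric(1L))
  expect_gt(mean(cover), 0.92)
  expect_lt(mean(cover), 0.98)
  # Chebyshev floor holds even for heavy-tailed data
  set.seed(41)
  d <- rt(200, df = 2)
  ba <- bland_altman(d, numeric(200), k = 1.96)
  expect_gte(1 - length(ba$outside_indices) / 200, 1 - 1 / 1.96^2)
})

test_that("summary statistics use sample SD and are permutation-invariant", {
  s <- summary_stats(c(1, 2, 3))
  expect_equal(s$mean, 2); expect_equal(s$median, 2); expect_equal(s$sd, 1)
  const <- summary_stats(rep(4.2, 9))
  expect_equal(const$sd, 0)
  expect_equal(const$q1, const$median)
  expect_equal(const$q3, const$median)
  set.seed(43)
  x <- rnorm(25)
  expect_identical(summary_stats(x), summary_stats(sample(x)))
  expect_error(summary_stats(numeric()), "insufficient data")
})

test_that("ratio summary is the per-pair ratio mean with a 2-SD interval", {
  a <- c(1, 2, 3)
  r <- ratio_summary(a, a)
  expect_equal(r$mean_ratio, 1); expect_equal(r$sd_ratio, 0)
  r2 <- ratio_summary(2 * a, a)
  expect_equal(r2$mean_ratio, 2)
  expect_equal(r2$interval_low, r2$mean_ratio - 2 * r2$sd_ratio)
  expect_error(ratio_summary(a, c(1, 0, 2)), "invalid ratio")
})

test_that("paired measurements validate their invariants", {
  expect_error(paired_measurements(1:3, 1:2), "equal length")
  expect_error(paired_measurements(numeric(), numeric()), "non-empty")
  expect_error(paired_measurements(c(1, NA), c(1, 2)), "complete")
  p <- paired_measurements(1:3, 4:6, labels = c("a", "b", "c"))
  w <- wilcoxon_signed_rank(p)
  expect_equal(w$w_minus, 6)
})
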