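test_that("signed-rank p-values match exhaustive enumeration on ordinal data", {
  set.seed(42)
  checked <- 0
  while (checked < 60) {
    n <- sample(3:10, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    if (all(a == b)) next
    expect_equal(wilcoxon_signed_rank(a, b)$p_value, brute_wilcoxon_p(b - a),
                 tolerance = 1e-12)
    checked <- checked + 1
  }
  # tie-free continuous data agree with the classical exact distribution
  set.seed(1)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               stats::wilcox.test(y, x, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("signed-rank handles zeros, swaps and degenerate input", {
  expect_true(wilcoxon_signed_rank(c(2, 2, 3), c(2, 2, 3))$degenerate)
  expect_equal(wilcoxon_signed_rank(c(2, 2, 3), c(2, 2, 3))$p_value, 1)
  set.seed(8)
  a <- sample(1:4, 30, replace = TRUE)
  b <- sample(1:4, 30, replace = TRUE)
  fw <- wilcoxon_signed_rank(a, b)
  bw <- wilcoxon_signed_rank(b, a)
  expect_equal(fw$signed, -bw$signed)
  expect_equal(fw$p_value, bw$p_value)
  # both zero conventions run and report their effective n
  pr <- wilcoxon_signed_rank(c(1, 1, 2, 3), c(1, 1, 3, 1), zero_method = "pratt")
  expect_equal(pr$n_effective, 2)
  # paired-score data frames are accepted directly
  ps <- paired_scores(score_ref = a, score_rt = b)
  expect_equal(wilcoxon_signed_rank(ps)$p_value, fw$p_value)
})

test_that("the paired t test matches hand arithmetic and flags degeneracy", {
  r <- paired_t(rep(0, 4), c(1, 2, 3, 4))   # mean 2.5, sd 1.2910, n 4
  expect_equal(r$statistic, 2.5 / (sd(1:4) / 2), tolerance = 1e-12)
  expect_equal(r$statistic, 3.873, tolerance = 1e-3)
  expect_equal(r$p_value, 0.0305, tolerance = 1e-2)
  expect_equal(r$mean_difference, 2.5)
  d <- paired_t(c(1, 2, 3), c(2, 3, 4))     # constant difference
  expect_true(d$degenerate)
})

test_that("ICC distinguishes absolute agreement from consistency", {
  expect_equal(icc_absolute(cbind(1:10, 1:10))$statistic, 1)
  shifted <- cbind(1:10, 1:10 + 5)
  expect_lt(icc_absolute(shifted, "ICC2")$statistic, 1)
  expect_equal(icc_absolute(shifted, "ICC3")$statistic, 1)
  # variance-component recovery: subject sd 1, rater noise sd 0.25
  # analytic ICC = 1 / (1 + 0.0625)
  set.seed(3)
  subj <- rnorm(500)
  ratings <- cbind(subj + rnorm(500, sd = 0.25), subj + rnorm(500, sd = 0.25))
  expect_lt(abs(icc_absolute(ratings)$statistic - 1 / 1.0625), 0.05)
  expect_true(icc_absolute(cbind(rep(1, 5), rep(1, 5)))$degenerate)
})

test_that("Cohen's kappa matches its closed form and chance behaviour", {
  expect_equal(cohen_kappa(c(1, 2, 3, 1), c(1, 2, 3, 1))$statistic, 1)
  # 2x2 confusion (a=30, b=10, c=10, d=50): po = 0.8, pe = 0.52
  r1 <- rep(c("x", "x", "y", "y"), c(30, 10, 10, 50))
  r2 <- rep(c("x", "y", "x", "y"), c(30, 10, 10, 50))
  expect_equal(cohen_kappa(r1, r2)$statistic, (0.8 - 0.52) / 0.48, tolerance = 1e-12)
  # linear weights reduce to unweighted for a binary scale
  expect_equal(cohen_kappa(r1, r2, weights = "linear")$statistic,
               cohen_kappa(r1, r2)$statistic)
  # independent raters drift to zero agreement
  set.seed(10)
  i1 <- sample(1:4, 4000, replace = TRUE)
  i2 <- sample(1:4, 4000, replace = TRUE)
  expect_lt(abs(cohen_kappa(i1, i2)$statistic), 0.05)
  expect_true(cohen_kappa(rep("a", 5), rep("a", 5))$degenerate)
})

test_that("median-range summaries follow the midpoint convention", {
  expect_equal(median_range(c(1, 2, 3)),
               tibble::tibble(median = 2, min = 1, max = 3, n = 3L))
  expect_equal(median_range(c(1, 2, 3, 4))$median, 2.5)
  # score distributions with 71 patients: 10x1 + 11x2 + 50x3 and 23/32/15/1
  rt_scores <- rep(1:3, c(10, 11, 50))
  ref_scores <- rep(1:4, c(23, 32, 15, 1))
  expect_equal(median_range(rt_scores)$median, 3)
  expect_equal(median_range(ref_scores)$median, 2)
  expect_equal(median_range(ref_scores)$max, 4)
  expect_error(median_range(numeric(0)), class = "cscine_insufficient_data")
})
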