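test_that("absolute percent error matches direct substitution", {
  expect_equal(absolute_percent_error(56, 56), 0)
  expect_equal(absolute_percent_error(110, 100), 10)
  expect_equal(absolute_percent_error(75, 60), 25)
  expect_equal(absolute_percent_error(50, 60), 100 / 6)
  expect_error(absolute_percent_error(50, 0), "positive")
  expect_error(absolute_percent_error(50, -5), "positive")
})

test_that("Tukey outer fences flag exactly the hand-computed sets", {
  expect_equal(tukey_extreme_outliers(c(1, 2, 3, 4, 5)), rep(FALSE, 5))
  # type-7 quartiles of 6 values: Q1 = 2.25, Q3 = 4.75, fence 4.75 + 7.5
  expect_equal(tukey_extreme_outliers(c(1, 2, 3, 4, 5, 100)),
               c(rep(FALSE, 5), TRUE))
  # degenerate IQR = 0 collapses the fence onto the quartile
  expect_equal(tukey_extreme_outliers(c(5, 5, 5, 5, 9)),
               c(rep(FALSE, 4), TRUE))
  expect_warning(out <- tukey_extreme_outliers(c(1, 2, 3)), "fewer than 4")
  expect_equal(out, rep(FALSE, 3))
})

test_that("outlier removal stays sane on unimodal error distributions", {
  set.seed(14)
  for (i in 1:20) {
    x <- abs(rnorm(sample(8:60, 1), 0, 5))
    expect_lte(sum(tukey_extreme_outliers(x)), ceiling(length(x) / 2))
  }
})

test_that("APE summaries report the table statistics", {
  s <- ape_summary(c(0, 0, 0))
  expect_equal(s$mape_pct, 0)
  expect_equal(s$iqr_pct, 0)
  s2 <- ape_summary(c(1, 2, 3, 4))
  expect_equal(s2$n, 4)
  expect_equal(s2$mape_pct, 2.5)
  expect_equal(s2$median_pct, 2.5)
  expect_equal(s2$iqr_pct, unname(diff(quantile(1:4, c(.25, .75)))))
  expect_error(ape_summary(numeric(0)), "no APE")
})

test_that("removing an extreme value lowers the reported maximum", {
  x <- c(1, 2, 3, 4, 5, 100)
  keep <- !tukey_extreme_outliers(x)
  expect_lt(ape_summary(x[keep])$max_pct, max(x))
})

test_that("Lin's CCC matches hand computations with 1/n moments", {
  x <- c(3, 7, 9, 12)
  expect_equal(lin_ccc(x, x)$ccc, 1)
  expect_equal(lin_ccc(c(-1, 0, 1), c(1, 0, -1))$ccc, -1)
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 4, 6))$ccc, 8 / 22,
               tolerance = 1e-12)
  expect_error(lin_ccc(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("CCC magnitude never exceeds the Pearson correlation", {
  set.seed(15)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    ccc <- lin_ccc(x, y)$ccc
    expect_lte(abs(ccc), abs(cor(x, y)) + 1e-12)
  }
})

test_that("Bland-Altman matches the hand example and its identities", {
  ba0 <- bland_altman(c(5, 5, 5), c(5, 5, 5))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_range, 0)
  d <- c(1, -1, 2, 0, 3)
  ba <- bland_altman(d, rep(0, 5))
  expect_equal(ba$bias, 1)
  expect_equal(ba$sd_diff, sd(d))
  expect_equal(ba$lower_loa, 1 - 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba$upper_loa, 1 + 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba$loa_range, 2 * 1.96 * sd(d), tolerance = 1e-12)
  expect_true(ba$bias_lo < ba$bias && ba$bias < ba$bias_hi)
  expect_true(ba$lower_loa_lo < ba$lower_loa &&
                ba$lower_loa < ba$lower_loa_hi)
  expect_error(bland_altman(c(1, 2), c(0, 0)), "at least 3")
})

test_that("the LOA reconstruction identity holds on random data", {
  set.seed(16)
  for (i in 1:20) {
    n <- sample(5:100, 1)
    x <- rnorm(n, 50, 5); y <- rnorm(n, 50, 5)
    ba <- bland_altman(x, y)
    expect_equal(ba$loa_range, 2 * 1.96 * sd(x - y),
                 tolerance = 1e-12)
  }
})

test_that("the bias CI covers an injected bias at its nominal rate", {
  set.seed(17)
  b <- 3.7
  covered <- vapply(1:1000, function(i) {
    d <- b + rnorm(200, 0, 4)
    ba <- bland_altman(d, rep(0, 200))
    ba$bias_lo <= b && b <= ba$bias_hi
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("the paired bias test behaves at its edges", {
  r <- paired_bias_test(c(-1, 1, -2, 2), n_comparisons = 6)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_equal(r$p_adj, 1)
  expect_false(r$significant)
  expect_error(paired_bias_test(rep(1, 5)), "degenerate")
  expect_error(paired_bias_test(1), "at least 2")
})

test_that("Bonferroni adjustment caps at one and scales small p-values", {
  set.seed(18)
  d <- rnorm(20, 5, 1)  # far from zero
  r1 <- paired_bias_test(d, n_comparisons = 1)
  r6 <- paired_bias_test(d, n_comparisons = 6)
  expect_equal(r6$p, r1$p)
  expect_equal(r6$p_adj, min(1, 6 * r1$p))
})
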