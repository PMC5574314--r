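test_that("group comparison edge cases and the printed-summary oracle", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  r <- compare_groups(x, x)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_equal(r$stars, "")

  # Welch t from printed summary statistics (mass contrast):
  # independent hand computation gives t = -3.96, p << 0.001
  a <- group_summary(mean = 348, sd = 160, n = 104)
  b <- group_summary(mean = 440, sd = 214, n = 156)
  r2 <- compare_groups(a, b)
  se <- sqrt(160^2 / 104 + 214^2 / 156)
  expect_equal(r2$t, (348 - 440) / se, tolerance = 1e-12)
  expect_lt(r2$p, 0.001)
  expect_equal(r2$stars, "***")

  # paired with zero differences
  r3 <- compare_groups(x, x, paired = TRUE)
  expect_equal(r3$t, 0)
  expect_equal(r3$p, 1)
  expect_equal(r3$kind, "paired")

  expect_error(compare_groups(x, x[1:3], paired = TRUE), "equal n")
  expect_error(group_summary(x = 1), "n must be")

  # sample-based unpaired equals stats::t.test (Welch)
  set.seed(9)
  y <- rnorm(12, 1); z <- rnorm(15, 1.5)
  r4 <- compare_groups(y, z)
  tt <- t.test(y, z)
  expect_equal(r4$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(r4$p, tt$p.value, tolerance = 1e-10)
})

test_that("star coding follows the 0.05/0.01/0.001 convention", {
  expect_equal(significance_stars(c(0.2, 0.04, 0.009, 0.0009)),
               c("", "*", "**", "***"))
})

test_that("type-I error of the unpaired test is ~5% over 1000 replicates", {
  set.seed(12)
  rejections <- 0L
  for (i in 1:1000) {
    a <- rnorm(20, 5, 2); b <- rnorm(20, 5, 2)
    if (compare_groups(a, b)$p < 0.05) rejections <- rejections + 1L
  }
  expect_gt(rejections / 1000, 0.03)
  expect_lt(rejections / 1000, 0.07)
})

test_that("empirical CDF behaves as a distribution function", {
  x <- c(3, 1, 4, 1, 5, 9, 2.6)
  F <- cdf_of_ratios(x)
  expect_equal(F(max(x)), 1)
  expect_equal(F(min(x) - 1), 0)
  expect_true(all(diff(F(sort(x))) >= 0))

  Fv <- cdf_of_ratios(7)
  expect_equal(Fv(6.99), 0); expect_equal(Fv(7), 1)

  expect_equal(cdf_of_ratios(x)(x), cdf_of_ratios(x)(x))
  expect_error(cdf_of_ratios(numeric(0)), "no ratios")

  # adding a constant shifts support, not shape
  G <- cdf_of_ratios(x + 10)
  expect_equal(F(sort(x)), G(sort(x) + 10))
})

test_that("size-ratio correlation: exact lines and the independence null", {
  len <- c(1, 2, 3, 4, 5)
  expect_equal(size_ratio_correlation(len, 2 * len), 1)
  expect_equal(size_ratio_correlation(len, -len + 10), -1)
  expect_error(size_ratio_correlation(len, rep(2, 5)), "constant")
  expect_error(size_ratio_correlation(1:2, 1:2), "n must be")

  # under independence at n ~ 1e4, |r| < 0.05 in >= 95% of seeds
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    r <- size_ratio_correlation(rnorm(9769, 2.34, 0.7), rnorm(9769, 100, 30))
    if (abs(r) < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 19)
})

test_that("drug-effect normalization is post/pre per cell", {
  pre <- data.frame(cell_id = c("a", "b", "c"), ratio = c(100, 80, 60),
                    count = c(10, 20, 0))
  post_same <- pre
  n1 <- normalize_drug_effect(pre, post_same)
  expect_equal(n1$ratio, c(1, 1, 1))

  post <- pre
  post$ratio <- pre$ratio / 2
  n2 <- normalize_drug_effect(pre, post)
  expect_equal(n2$ratio, c(0.5, 0.5, 0.5))
  expect_true(n2$undefined[3])       # zero pre count flagged
  expect_true(is.na(n2$count[3]))

  expect_error(normalize_drug_effect(pre, post[1:2, ]), "pair")
})
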