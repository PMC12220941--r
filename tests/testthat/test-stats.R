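test_that("group summaries use median and Tukey hinges", {
  s <- summarize_group(c(1, 2, 3, 4, 5), "demo")
  expect_equal(s$median, 3)
  expect_equal(s$iqr_low, 2)
  expect_equal(s$iqr_high, 4)
  single <- summarize_group(7)
  expect_equal(unlist(single[c("median", "iqr_low", "iqr_high")]),
               c(median = 7, iqr_low = 7, iqr_high = 7))
  # a group built to have a known median
  vals <- c(58.09, 52.63, 73.76, 40.1, 55.2, 60.3, 58.09, 49.9, 70.2,
            51.0, 66.6)
  expect_equal(summarize_group(vals)$median, 58.09)
  expect_error(summarize_group(NA_real_), "no non-missing")
})

test_that("summaries are permutation invariant and affine equivariant", {
  set.seed(31)
  x <- rnorm(11)
  s1 <- summarize_group(x)
  s2 <- summarize_group(sample(x))
  expect_equal(s1[-1], s2[-1])
  s3 <- summarize_group(2.5 * x + 4)
  expect_equal(s3$median, 2.5 * s1$median + 4)
  expect_equal(s3$iqr_low, 2.5 * s1$iqr_low + 4)
})

test_that("the normality gate picks the documented test path", {
  set.seed(32)
  a <- rnorm(8); b <- rnorm(8) + 1
  expect_identical(compare_two_groups(a, b)$test_name,
                   "t_unpaired_two_tailed")
  skewed <- c(0.01, 0.02, 0.03, 0.05, 0.1, 4, 30, 200)
  res <- compare_two_groups(skewed, skewed + 0.001)
  expect_identical(res$test_name, "wilcoxon_rank_sum_two_tailed")
  expect_lt(res$normality_p[["a"]], 0.05)
  # deterministic given the data
  expect_identical(compare_two_groups(a, b)$p_value,
                   compare_two_groups(a, b)$p_value)
  expect_error(compare_two_groups(1:2, 1:5), "n >= 3")
})

test_that("the exact Wilcoxon path matches complete enumeration", {
  res <- compare_two_groups(c(1, 2, 3, 4), c(101, 102, 103, 104),
                            test = "wilcoxon")
  expect_equal(res$p_value, 2 / 70)
  ident <- compare_two_groups(c(5, 6, 7), c(5, 6, 7), test = "wilcoxon")
  expect_equal(ident$p_value, 1)
  set.seed(33)
  for (rep in 1:12) {
    na <- sample(3:6, 1); nb <- sample(3:(12 - na), 1)
    a <- round(rnorm(na), 3); b <- round(rnorm(nb, 0.5), 3)
    if (anyDuplicated(c(a, b))) next
    expect_equal(compare_two_groups(a, b, test = "wilcoxon")$p_value,
                 wilcoxon_enum_p(a, b), tolerance = 1e-12)
  }
})

test_that("the two-group test holds its nominal type-I error", {
  set.seed(34)
  reject <- replicate(1000, {
    compare_two_groups(rnorm(8), rnorm(8))$p_value < 0.05
  })
  expect_gt(mean(reject), 0.03)
  expect_lt(mean(reject), 0.07)
})

test_that("Tukey HSD compares all pairs with family-wise control", {
  g <- rep(c("x", "y", "z"), each = 6)
  same <- c(rnorm(18))
  set.seed(35)
  res <- tukey_hsd_groups(rep(c(0.1, 0.2, 0.15, 0.12, 0.18, 0.11), 3), g)
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_adjusted > 0.9))

  set.seed(36)
  vals <- c(rnorm(6), rnorm(6), rnorm(6) + 10)
  shifted <- tukey_hsd_groups(vals, g)
  expect_lt(shifted$p_adjusted[shifted$group_1 == "z" &
                                 shifted$group_2 == "x"], 0.001)
  expect_error(tukey_hsd_groups(rnorm(12), rep(c("x", "y"), 6)),
               "compare_two_groups")

  set.seed(37)
  fw <- replicate(1000, {
    any(tukey_hsd_groups(rnorm(18), g)$p_adjusted < 0.05)
  })
  expect_gt(mean(fw), 0.03)
  expect_lt(mean(fw), 0.07)
})

test_that("dampening ratio divides treated by control medians", {
  expect_equal(dampening_ratio(58.09, 107.86), 53.855, tolerance = 1e-4)
  expect_equal(dampening_ratio(summarize_group(c(4, 5, 6)),
                               summarize_group(c(9, 10, 11))), 50)
  expect_equal(dampening_ratio(34.41, 61.92), 55.57, tolerance = 1e-3)
  expect_equal(dampening_ratio(10, 10), 100)
  expect_error(dampening_ratio(5, 0), "positive")
})
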