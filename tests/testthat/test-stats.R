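# Paired tests (Shapiro-gated t / Wilcoxon) and Bland-Altman agreement.

test_that("exact Wilcoxon enumeration reproduces hand-enumerated p-values", {
  expect_equal(wilcoxon_exact(1), 1.0)
  expect_equal(wilcoxon_exact(c(1, 2, 3)), 0.25)   # W+ = 6 is the unique extreme
  expect_equal(wilcoxon_exact(c(-1, 1)), 1.0)      # tied symmetric pair
  expect_error(wilcoxon_exact(c(0, 0)), "zero")
})

test_that("the DP distribution agrees exactly with full enumeration", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(3:12, 1)
    d <- round(stats::rnorm(n), sample(0:1, 1))  # occasional ties/zeros
    if (all(d == 0)) d[1] <- 1
    p_enum <- wilcoxon_exact(d)
    p_dp <- wilcoxon_signed(d, method = "exact")$p_value
    expect_equal(p_dp, p_enum, tolerance = 1e-12)
  }
})

test_that("exact p-values agree with the reference implementation", {
  set.seed(19)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    d <- stats::rnorm(n)  # continuous: no ties, no zeros
    ours <- wilcoxon_signed(d, method = "exact")$p_value
    ref <- stats::wilcox.test(d, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("the corrected normal approximation is accurate at the exact cutoff", {
  set.seed(23)
  worst <- 0
  for (i in 1:200) {
    n <- sample(10:12, 1)
    d <- stats::rnorm(n)
    p_ex <- wilcoxon_signed(d, method = "exact")$p_value
    p_no <- wilcoxon_signed(d, method = "normal")$p_value
    worst <- max(worst, abs(p_ex - p_no))
  }
  expect_lt(worst, 0.01)
})

test_that("paired_compare handles identical, degenerate and shifted data", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  r <- paired_compare(x, x)
  expect_equal(r$p_value, 1)
  expect_equal(r$delta_mean, 0)
  expect_identical(r$test_used, "sign_symmetric")
  xi <- c(1, 3, 2, 5, 4)   # integer-valued so the shift is exactly constant
  expect_error(paired_compare(xi, xi + 2), "degenerate")
  expect_error(paired_compare(1:2, 2:3), "n >= 3")
  expect_error(paired_compare(1:4, 1:5), "equal length")
  # a large shift against small noise is detected decisively
  set.seed(41)
  pre <- stats::rnorm(20, 10, 1)
  post <- pre + 5 + stats::rnorm(20, 0, 0.5)
  expect_lt(paired_compare(pre, post)$p_value, 0.001)
})

test_that("the Shapiro gate selects the appropriate test", {
  set.seed(43)
  pre <- stats::rnorm(30, 10, 1)
  r_norm <- paired_compare(pre, pre + stats::rnorm(30, 0.2, 0.5))
  expect_identical(r_norm$test_used, "paired_t")
  r_skew <- paired_compare(pre, pre + stats::rexp(30, 1 / 3)^2)
  expect_identical(r_skew$test_used, "wilcoxon")
})

test_that("Bland-Altman reproduces the hand-worked absolute example", {
  ba <- bland_altman(c(1, 2, 3), c(1.1, 1.9, 3.2), type = "absolute")
  # differences (ref - test): -0.1, 0.1, -0.2
  expect_equal(ba$bias, mean(c(-0.1, 0.1, -0.2)), tolerance = 1e-12)
  expect_equal(ba$bias, -0.0667, tolerance = 1e-3)
  expect_equal(ba$sd, stats::sd(c(-0.1, 0.1, -0.2)), tolerance = 1e-12)
  expect_equal(ba$sd, 0.1528, tolerance = 1e-3)
  expect_equal(ba$loa_low, -0.3661, tolerance = 1e-3)
  expect_equal(ba$loa_high, 0.2327, tolerance = 1e-3)
  expect_equal(ba$loa_high, ba$bias + 1.96 * ba$sd, tolerance = 1e-12)
})

test_that("Bland-Altman degenerate and shift behaviour", {
  x <- c(0.7, 0.8, 0.9, 0.85)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0); expect_equal(ba0$sd, 0)
  expect_equal(ba0$pct_within_loa, 1)
  # absolute differences: adding a constant to the test values shifts the
  # bias by that constant and leaves the SD unchanged
  ba1 <- bland_altman(x, x + 0.05, type = "absolute")
  ba2 <- bland_altman(x, x + 0.15, type = "absolute")
  expect_equal(ba1$bias - ba2$bias, 0.1, tolerance = 1e-12)
  expect_equal(ba1$sd, ba2$sd, tolerance = 1e-12)
  expect_error(bland_altman(c(1, -1), c(-1, 1), type = "percent"), "zero")
  expect_error(bland_altman(1:3, 1:2), "equal length")
})
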