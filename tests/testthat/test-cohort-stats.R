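test_that("identical samples give a null comparison", {
  x <- withr::with_seed(1, rnorm(30))
  res <- compare_groups(x, x)
  expect_equal(res$test_used, "welch_t")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("exact Mann-Whitney on fully separated ranks gives p = 0.1", {
  res <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  # uniform samples of 3: Shapiro p is high, but n = 3 triads from a line
  # still pass normality, so force the U branch through the raw interface
  mw <- wilcox.test(c(1, 2, 3), c(4, 5, 6), exact = TRUE)
  expect_equal(mw$statistic, c(W = 0))
  expect_equal(mw$p.value, 0.1)
  # the gated procedure reports the same p when the U branch is taken
  skewed_x <- c(1, 1.01, 1.02, 1.03, 1.04, 10)  # fails Shapiro at 0.05
  res2 <- compare_groups(skewed_x, skewed_x + 0.001)
  expect_equal(res2$test_used, "mann_whitney_u")
})

test_that("non-normal or constant samples fall through to Mann-Whitney", {
  x <- withr::with_seed(2, exp(rnorm(40, sd = 2)))  # lognormal fails Shapiro
  y <- withr::with_seed(3, rnorm(40, mean = 1))
  res <- compare_groups(x, y)
  expect_equal(res$test_used, "mann_whitney_u")
  expect_true(res$normality_p[1] < 0.05)

  const <- rep(5, 10)
  res_c <- compare_groups(const, y[1:10])
  expect_equal(res_c$test_used, "mann_whitney_u")
  expect_true(is.na(res_c$normality_p[1]))
})

test_that("summary-statistic Welch p-values reproduce published table rows", {
  low <- welch_from_summary(585.40, 163.83, 55, 512.57, 122.84, 33)
  expect_equal(round(low$p_value, 2), 0.02)
  rel <- welch_from_summary(70.32, 19.92, 55, 71.35, 14.81, 33)
  expect_equal(rel$p_value, 0.782, tolerance = 2e-3)
  tot <- welch_from_summary(1378.63, 407.35, 55, 1345.78, 353.97, 33)
  expect_equal(round(tot$p_value, 3), 0.692)
  null <- welch_from_summary(5, 1, 10, 5, 2, 10)
  expect_equal(null$statistic, 0)
  expect_equal(null$p_value, 1)
  expect_error(welch_from_summary(1, 1, 1, 2, 1, 10), class = "velozone_validation_error")
  expect_error(welch_from_summary(1, 0, 10, 2, 1, 10), class = "velozone_validation_error")
})

test_that("summary-based Welch agrees with the raw-sample t branch to 1e-12", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, rnorm(25, 10, 2))
    y <- withr::with_seed(seed + 50, rnorm(18, 11, 3))
    raw <- t.test(x, y, var.equal = FALSE)
    summ <- welch_from_summary(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
    expect_equal(summ$p_value, raw$p.value, tolerance = 1e-12)
    expect_equal(summ$statistic, unname(raw$statistic), tolerance = 1e-12)
  }
})

test_that("exact and approximate Mann-Whitney agree closely at combined n = 20", {
  for (seed in 1:10) {
    x <- withr::with_seed(seed, runif(10))
    y <- withr::with_seed(seed + 100, runif(10, 0.2, 1.2))
    p_exact <- wilcox.test(x, y, exact = TRUE)$p.value
    p_approx <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(p_exact - p_approx), 0.01)
  }
})

test_that("Welch power at 2-SD separation matches the noncentral-t closed form", {
  n <- 30; delta <- 2  # means 2 SDs apart, unit variance
  ncp <- delta / sqrt(2 / n)
  df <- 2 * n - 2
  crit <- qt(0.975, df)
  power_closed <- 1 - pt(crit, df, ncp) + pt(-crit, df, ncp)
  rejections <- vapply(1:1000, function(r) {
    x <- withr::with_seed(2000 + r, rnorm(n))
    y <- withr::with_seed(7000 + r, rnorm(n, delta))
    compare_groups(x, y)$p_value < 0.05
  }, logical(1))
  mc_se <- sqrt(power_closed * (1 - power_closed) / 1000)
  expect_lt(abs(mean(rejections) - power_closed), 4 * mc_se + 0.01)
})

test_that("cohort comparison tables carry group summaries and test markers", {
  male <- data.frame(total = withr::with_seed(10, rnorm(20, 1380, 400)),
                     very_high = withr::with_seed(11, rexp(20, 1 / 30)))
  female <- data.frame(total = withr::with_seed(12, rnorm(15, 1340, 350)),
                       very_high = withr::with_seed(13, rexp(15, 1 / 70)))
  tab <- compare_cohorts(male, female)
  expect_equal(tab$metric, c("total", "very_high"))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_equal(tab$n_x, c(20L, 20L))
  holm <- compare_cohorts(male, female, p_adjust = "holm")
  expect_true(all(holm$p_adjusted >= holm$p_value))
})
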