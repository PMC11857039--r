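test_that("the Shapiro-Wilk gate routes skewed data to the nonparametric branch", {
  set.seed(14)
  skew <- list(a = exp(rnorm(50)))
  gs <- shapiro_gate(skew)
  expect_lte(gs$table$p, 0.001)
  expect_true(gs$nonparametric)
  set.seed(14)
  norm <- list(a = rnorm(50))
  gn <- shapiro_gate(norm)
  expect_gt(gn$table$p, 0.05)
  expect_false(gn$nonparametric)
  gc <- shapiro_gate(list(a = rep(1, 10)))
  expect_false(gc$table$normal)
  expect_true(gc$nonparametric)
  expect_warning(shapiro_gate(list(a = c(1, 2))), "n = 2")
})

test_that("Friedman chi-square matches the rank formula and the reference implementation", {
  # 3 blocks x 3 conditions with ranks (1,2,3) in every block -> chi2 = 6
  m3 <- matrix(rep(c(1, 2, 3), each = 3), 3, 3)
  fb3 <- friedman_bonferroni(m3)
  expect_equal(fb3$statistic, 6)
  # identical conditions within every block -> statistic 0, p = 1
  m0 <- matrix(rep(1:4, 5), 4, 5)
  fb0 <- friedman_bonferroni(m0)
  expect_equal(fb0$statistic, 0)
  expect_equal(fb0$p, 1)
  # agreement with stats::friedman.test, with and without ties
  set.seed(3)
  for (i in 1:5) {
    m <- matrix(rnorm(6 * 10), 6, 10)
    if (i > 2) m <- round(m)  # induce ties
    fb <- friedman_bonferroni(m)
    ft <- friedman.test(m)
    expect_equal(fb$statistic, unname(ft$statistic))
    expect_equal(fb$p, ft$p.value)
  }
})

test_that("Friedman statistic is invariant under within-block monotone transforms", {
  set.seed(8)
  m <- matrix(rnorm(48), 6, 8)
  s0 <- friedman_bonferroni(m)$statistic
  expect_equal(friedman_bonferroni(exp(m))$statistic, s0)
  expect_equal(friedman_bonferroni(m^3)$statistic, s0)
})

test_that("incomplete blocks are dropped listwise and degenerate input is refused", {
  set.seed(5)
  m <- matrix(rnorm(40), 4, 10)
  m[2, 3] <- NA
  expect_message(fb <- friedman_bonferroni(m), "incomplete")
  expect_equal(fb$n_blocks, 3)
  m2 <- matrix(c(1, NA, NA, 2, NA, NA), 3, 2)
  expect_warning(expect_message(fbad <- friedman_bonferroni(m2)), "not run")
  expect_true(is.na(fbad$p))
})

test_that("post hoc p values are Bonferroni-adjusted, capped, and exceed raw p", {
  set.seed(6)
  m <- matrix(rnorm(60), 6, 10)
  m[, 1] <- m[, 1] + 3
  fb <- friedman_bonferroni(m)
  expect_equal(nrow(fb$posthoc), choose(10, 2))
  expect_true(all(fb$posthoc$p_adj >= fb$posthoc$p_raw))
  expect_true(all(fb$posthoc$p_adj <= 1))
  expect_true(all(fb$posthoc$p_raw >= 0 & fb$posthoc$p_raw <= 1))
  fbc <- friedman_bonferroni(m, comparisons = "vs_control")
  expect_equal(nrow(fbc$posthoc), 9)
  fw <- friedman_bonferroni(m, posthoc = "wilcoxon")
  expect_equal(nrow(fw$posthoc), 45)
  expect_true(all(fw$posthoc$p_adj >= fw$posthoc$p_raw, na.rm = TRUE))
})

test_that("Mann-Whitney: exact p for full separation, p = 1 for identical samples", {
  # completely separated n = 6 vs 6: U = 0, exact p = 2 * 6! * 6! / 12!
  mw <- mannwhitney_timepoints(1:6, 101:106)
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 2 * factorial(6)^2 / factorial(12))
  ident <- mannwhitney_timepoints(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$p, 1)
  expect_warning(miss <- mannwhitney_timepoints(numeric(0), 1:3), "empty")
  expect_true(is.na(miss$p))
})

test_that("Mann-Whitney detects a 2-SD shift at n = 6 in most replicates", {
  set.seed(77)
  rej <- mean(replicate(500, {
    mannwhitney_timepoints(rnorm(6), rnorm(6, 2))$p <= 0.05
  }))
  expect_gte(rej, 0.8)
})

test_that("Spearman rho reproduces hand values and flags degenerate pairs", {
  expect_equal(spearman_rho(1:5, 2 * (1:5))$rho, 1)
  expect_equal(spearman_rho(1:5, rev(1:5))$rho, -1)
  expect_equal(spearman_rho(1:5, c(1, 3, 2, 5, 4))$rho, 0.8)
  expect_true(is.na(spearman_rho(1:5, rep(2, 5))$rho))
  df <- data.frame(condition = rep(c("A", "B"), each = 5),
                   timepoint = 4,
                   BF = rep(1:5, 2), BIC = c(1, 3, 2, 5, 4, 5:1))
  grid <- spearman_grid(df, list(c("BF", "BIC")))
  expect_equal(grid$rho[grid$condition == "A"], 0.8)
  expect_equal(grid$rho[grid$condition == "B"], -1)
})

test_that("family-wise alpha arithmetic divides the error rate", {
  expect_equal(round(100 * bonferroni_alpha(0.05, 14), 2), 0.36)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 10), 0.005)
  expect_error(bonferroni_alpha(0.05, 0), "positive")
})

test_that("group descriptives report mean and SD per group", {
  d <- describe_groups(list(a = c(1, 2, 3), b = c(10, 10)))
  expect_equal(d$mean, c(2, 10))
  expect_equal(d$sd[1], 1)
  expect_equal(d$n, c(3, 2))
})
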