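test_that("two-group comparison matches frozen reference values", {
  fx <- fixture_groups()
  cmp <- compare_groups(fx$a, fx$b, group_names = c("pad", "control"))
  # both samples pass the normality gate -> Student's t branch
  expect_equal(cmp$test_used, "t")
  expect_equal(cmp$statistic, fx$t_stat, tolerance = 1e-10)
  expect_equal(cmp$p_value, fx$t_p, tolerance = 1e-10)
  # force the rank branch by gating at alpha = 1 is not allowed (alpha is a
  # probability), so compare the Wilcoxon p on the same fixture directly
  w <- stats::wilcox.test(fx$a, fx$b)
  expect_equal(w$p.value, fx$mww_p, tolerance = 1e-10)
})

test_that("comparison branches and invariances behave as specified", {
  set.seed(51)
  a <- rnorm(20, 10, 1)
  # identical samples: p = 1 on either branch
  expect_equal(compare_groups(a, a)$p_value, 1, tolerance = 1e-6)
  # separated groups: tiny p
  expect_lt(compare_groups(a, a + 1000)$p_value, 1e-3)
  # group order changes the sign of the statistic, not the p-value
  b <- rnorm(20, 11, 1)
  c1 <- compare_groups(a, b)
  c2 <- compare_groups(b, a)
  expect_equal(c1$p_value, c2$p_value, tolerance = 1e-12)
  # skewed data fails the gate -> Mann-Whitney branch with median (IQR)
  skewed_a <- exp(rnorm(30, 0, 1.5))
  skewed_b <- exp(rnorm(30, 0.3, 1.5))
  cmp <- compare_groups(skewed_a, skewed_b)
  expect_equal(cmp$test_used, "mann_whitney")
  expect_match(cmp$summary[[1]], "\\(")
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "insufficient data")
})

test_that("categorical gate reproduces the study's smoking-history p-value", {
  smoking <- matrix(c(16, 8, 2, 11), 2)   # smokers / non-smokers by group
  res <- categorical_test(smoking)
  expect_equal(res$test_used, "fisher")   # observed cell 2 < 5
  expect_equal(res$p_value, 0.0051372682073460721, tolerance = 1e-10)
  expect_equal(res$p_value, stats::fisher.test(smoking)$p.value,
               tolerance = 1e-12)
})

test_that("categorical tests match enumeration and handle balance", {
  # balanced table: no association, p = 1 (chi-square branch, all cells 5)
  expect_equal(categorical_test(matrix(5, 2, 2))$p_value, 1)
  # diagonal table: Fisher equals the hypergeometric tail enumeration
  res <- categorical_test(matrix(c(10, 0, 0, 10), 2))
  expect_equal(res$test_used, "fisher")
  # both extreme tables have probability 1/choose(20,10)
  expect_equal(res$p_value, 2 * stats::dhyper(10, 10, 10, 10),
               tolerance = 1e-12)
  # large balanced-expected table goes through Pearson chi-square
  res2 <- categorical_test(matrix(c(12, 7, 8, 15), 2))
  expect_equal(res2$test_used, "chi_square")
  expect_equal(res2$statistic, 3.3586020386935722, tolerance = 1e-10)
  expect_equal(res2$p_value, 0.066854799133611864, tolerance = 1e-10)
  expect_error(categorical_test(matrix(0, 2, 2)), "all-zero")
  expect_error(categorical_test(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("univariate regression matches closed-form and frozen references", {
  fx <- fixture_ols()
  fit <- univariate_regression(fx$y, fx$x)
  ref <- oracle_ols(fx$y, fx$x)
  expect_equal(fit$slope_raw, ref$slope, tolerance = 1e-10)
  expect_equal(fit$slope_se, ref$se, tolerance = 1e-10)
  expect_equal(fit$r2, ref$r2, tolerance = 1e-10)
  expect_equal(fit$p_value, ref$p, tolerance = 1e-10)
  expect_equal(fit$beta_std, ref$beta_std, tolerance = 1e-10)
  # frozen independent values (scipy.stats.linregress)
  expect_equal(fit$slope_raw, fx$slope, tolerance = 1e-10)
  expect_equal(fit$slope_se, fx$se, tolerance = 1e-10)
  expect_equal(fit$r2, fx$r2, tolerance = 1e-10)
  expect_equal(fit$p_value, fx$p, tolerance = 1e-10)
})

test_that("regression identities and edge cases hold", {
  # exact line: standardized beta 1, R2 1 (lm warns about the perfect fit)
  fit <- suppressWarnings(univariate_regression(2 * (1:10), 1:10))
  expect_equal(fit$beta_std, 1, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_lt(fit$p_value, 1e-12)
  # R2 = beta_std^2 = cor^2 for any data
  set.seed(61)
  for (i in 1:5) {
    y <- rnorm(15); x <- rnorm(15)
    f <- univariate_regression(y, x)
    expect_equal(f$r2, f$beta_std^2, tolerance = 1e-12)
    expect_equal(f$r2, cor(y, x)^2, tolerance = 1e-12)
    expect_equal(f$adj_r2, 1 - (1 - f$r2) * 14 / 13, tolerance = 1e-12)
  }
  # near-independent data can produce negative adjusted r2
  set.seed(62)
  f0 <- univariate_regression(rnorm(30), rnorm(30))
  expect_lt(f0$adj_r2, f0$r2)
  expect_error(univariate_regression(rnorm(5), rep(3, 5)),
               "degenerate predictor")
  expect_error(univariate_regression(c(1, 2), c(1, 2)), "insufficient")
})

test_that("ICC(A,k) matches frozen pingouin values and direct ANOVA arithmetic", {
  fx <- fixture_icc()
  res <- icc_twoway(fx$ratings)
  expect_equal(res$icc, fx$icc_ak, tolerance = 1e-10)
  expect_equal(res$icc, oracle_icc_ak(fx$ratings), tolerance = 1e-12)
  expect_equal(round(c(res$ci_low, res$ci_high), 2), fx$ci_ak,
               tolerance = 0.005)
  expect_true(res$ci_low <= res$icc && res$icc <= res$ci_high)
  expect_true(res$excellent)
  resc <- icc_twoway(fx$ratings, type = "consistency")
  expect_equal(resc$icc, fx$icc_ck, tolerance = 1e-10)
})

test_that("ICC properties: identity, offsets, invariance, independence", {
  set.seed(71)
  r1 <- rnorm(12, 1500, 200)
  # identical raters: exactly 1
  expect_identical(icc_twoway(cbind(r1, r1))$icc, 1)
  # constant offset with growing between-target variance: approaches 1
  spread <- function(s) {
    targets <- rnorm(10, 0, s)
    icc_twoway(cbind(targets, targets + 5))$icc
  }
  set.seed(72)
  expect_gt(spread(200), spread(5))
  set.seed(73)
  expect_gt(spread(500), 0.99)
  # agreement penalises an offset; consistency does not
  set.seed(74)
  targets <- rnorm(8, 0, 3)
  m <- cbind(targets, targets + 4)
  expect_lt(icc_twoway(m)$icc, icc_twoway(m, type = "consistency")$icc)
  expect_equal(icc_twoway(m, type = "consistency")$icc, 1,
               tolerance = 1e-12)
  # shift/scale invariance
  set.seed(75)
  mm <- matrix(rnorm(40, 10, 2), 20, 2)
  base <- icc_twoway(mm)
  shifted <- icc_twoway(mm + 100)
  scaled <- icc_twoway(mm * 3.7)
  expect_equal(base$icc, shifted$icc, tolerance = 1e-12)
  expect_equal(base$icc, scaled$icc, tolerance = 1e-12)
  expect_equal(base$ci_low, scaled$ci_low, tolerance = 1e-12)
  # independent columns: ICC near 0 and CI covers 0
  set.seed(76)
  ind <- cbind(rnorm(20), rnorm(20))
  res <- icc_twoway(ind)
  expect_lt(abs(res$icc), 0.6)
  expect_lt(res$ci_low, 0)
  expect_gt(res$ci_high, 0)
  expect_error(icc_twoway(cbind(c(1, NA, 3), c(1, 2, 3))), "missing data")
  expect_error(icc_twoway(matrix(1:3, 3, 1)), "at least 2")
})

test_that("cohort-level tables assemble per-variable results", {
  set.seed(81)
  df <- data.frame(group = rep(c("pad", "control"), each = 15),
                   ecv = c(rnorm(15, 26, 5), rnorm(15, 17, 5)),
                   t1 = c(rnorm(15, 1900, 40), rnorm(15, 1820, 60)),
                   abi = c(rnorm(15, 0.7, 0.2), rnorm(15, 1.16, 0.09)))
  tab <- group_comparison_table(df, c("ecv", "t1"), "group")
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_true(all(tab$test %in% c("t", "mann_whitney")))
  reg <- regression_table(df, responses = c("ecv", "t1"),
                          predictors = "abi")
  expect_equal(nrow(reg), 2)
  f <- univariate_regression(df$ecv, df$abi)
  expect_equal(reg$beta_std[reg$response == "ecv"], f$beta_std)
})
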