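#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk is applied to each group; when both groups look normal at
#' the gate level `alpha` the groups are compared with an independent-sample
#' Student's t-test (equal variances), otherwise with the two-sided
#' Mann-Whitney-Wilcoxon test. Summaries are formatted to match the branch:
#' mean +/- sd for the t branch, median (IQR) otherwise.
#'
#' @param values_a,values_b Numeric samples for the two groups (n >= 3
#'   each).
#' @param alpha Shapiro-Wilk gate level.
#' @param variable Optional variable name carried into the result.
#' @param group_names Length-2 character vector of group labels.
#' @return An object of class `"group_comparison"`: a list with
#'   `test_used` (`"t"` or `"mann_whitney"`), `p_value`, `statistic`,
#'   `normality_p` (per group), per-group summaries and formatted summary
#'   strings.
#' @examples
#' compare_groups(rnorm(10), rnorm(10) + 2)
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05,
                           variable = "value",
                           group_names = c("A", "B")) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  if (length(values_a) < 3 || length(values_b) < 3) {
    stop("insufficient data: each group needs at least 3 finite values",
         call. = FALSE)
  }
  sw <- c(.shapiro_p(values_a), .shapiro_p(values_b))
  normal <- all(sw >= alpha)
  if (normal) {
    ht <- stats::t.test(values_a, values_b, var.equal = TRUE)
    test_used <- "t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                              exact = NULL, correct = TRUE))
    test_used <- "mann_whitney"
  }
  summ <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    list(n = length(x), mean = mean(x), sd = stats::sd(x),
         median = q[2], q1 = q[1], q3 = q[3])
  }
  fmt <- function(s) {
    if (normal) {
      sprintf("%.3g ± %.3g", s$mean, s$sd)
    } else {
      sprintf("%.3g (%.3g–%.3g)", s$median, s$q1, s$q3)
    }
  }
  sa <- summ(values_a); sb <- summ(values_b)
  structure(
    list(variable = variable, test_used = test_used,
         p_value = unname(ht$p.value), statistic = unname(ht$statistic),
         normality_p = stats::setNames(sw, group_names),
         groups = stats::setNames(list(sa, sb), group_names),
         summary = stats::setNames(c(fmt(sa), fmt(sb)), group_names),
         alpha = alpha),
    class = "group_comparison"
  )
}

# Shapiro-Wilk needs 3 <= n <= 5000 and non-constant data; a constant
# sample is maximally non-normal for the gate's purposes.
.shapiro_p <- function(x) {
  if (stats::sd(x) == 0) return(0)
  stats::shapiro.test(x)$p.value
}

#' @export
print.group_comparison <- function(x, ...) {
  lab <- if (x$test_used == "t") "Student's t-test" else
    "Mann-Whitney-Wilcoxon"
  cat(sprintf("%s: %s vs %s\n", x$variable, names(x$groups)[1],
              names(x$groups)[2]))
  cat(sprintf("  %s (Shapiro-Wilk p = %.3g, %.3g)\n", lab,
              x$normality_p[1], x$normality_p[2]))
  cat(sprintf("  %s: %s | %s: %s\n", names(x$summary)[1], x$summary[1],
              names(x$summary)[2], x$summary[2]))
  cat(sprintf("  p = %.4g\n", x$p_value))
  invisible(x)
}

#' Chi-square or Fisher exact test for a contingency table
#'
#' For 2 x 2 tables the Fisher exact test is used whenever any observed or
#' expected cell count is below 5 (matching the convention behind the
#' study-style reporting); otherwise the Pearson chi-square test without
#' continuity correction. Larger 2 x k tables use Fisher only when an
#' expected count is below 5.
#'
#' @param table A matrix of non-negative integer counts (2 x 2 or 2 x k).
#' @return A list with `p_value`, `test_used` (`"chi_square"` or
#'   `"fisher"`), and `statistic` (chi-square only).
#' @examples
#' categorical_test(matrix(c(16, 8, 2, 11), 2))
#' @export
categorical_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("invalid input: counts must be non-negative integers",
         call. = FALSE)
  }
  if (sum(table) == 0) {
    stop("invalid input: all-zero table", call. = FALSE)
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  small <- any(expected < 5) ||
    (all(dim(table) == 2) && any(table < 5))
  if (small) {
    ht <- stats::fisher.test(table)
    list(p_value = ht$p.value, test_used = "fisher", statistic = NA_real_)
  } else {
    ht <- stats::chisq.test(table, correct = FALSE)
    list(p_value = unname(ht$p.value), test_used = "chi_square",
         statistic = unname(ht$statistic))
  }
}

#' Univariate linear regression with study-style reporting
#'
#' Ordinary least squares `y = a + b x`, reporting both the raw slope with
#' its standard error and the standardized coefficient
#' `beta = b * sd(x) / sd(y)`, together with R-squared, the adjusted
#' r-squared `1 - (1 - R2)(n - 1)/(n - 2)` (which can be negative), and the
#' two-sided p-value for the slope. Rows with missing values in either
#' variable are dropped pairwise.
#'
#' @param y,x Response and predictor vectors of equal length.
#' @return An object of class `"uni_reg"`: a list with `n`, `intercept`,
#'   `slope_raw`, `slope_se`, `beta_std`, `r2`, `adj_r2`, `p_value`.
#' @examples
#' univariate_regression(c(2.1, 3.9, 6.2, 7.8, 10.1), 1:5)
#' @export
univariate_regression <- function(y, x) {
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]; x <- x[keep]
  n <- length(y)
  if (n < 3) {
    stop("insufficient data: need at least 3 complete pairs", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("degenerate predictor: 'x' is constant", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  se <- sm$coefficients[2, 2]
  r2 <- sm$r.squared
  structure(
    list(n = n,
         intercept = unname(stats::coef(fit)[1]),
         slope_raw = slope,
         slope_se = se,
         beta_std = slope * stats::sd(x) / stats::sd(y),
         r2 = r2,
         adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2),
         p_value = sm$coefficients[2, 4]),
    class = "uni_reg"
  )
}

#' @export
print.uni_reg <- function(x, ...) {
  cat(sprintf(
    "Univariate OLS (n = %d): beta_std = %.3f, slope = %.4g (SE %.4g)\n",
    x$n, x$beta_std, x$slope_raw, x$slope_se))
  cat(sprintf("  R2 = %.3g, adj r2 = %.3g, p = %.4g\n", x$r2, x$adj_r2,
              x$p_value))
  invisible(x)
}

#' Two-way random-effects average-measures intraclass correlation
#'
#' ICC from the two-way ANOVA decomposition of an `n x k` ratings matrix
#' (targets in rows, raters/occasions in columns), in the average-measures
#' form: absolute agreement ICC(A,k) by default, or consistency ICC(C,k).
#' The 95% confidence interval uses the F-based intervals of the
#' two-way random-effects model (McGraw-Wong), with the single-measure
#' bounds mapped to average measures by the Spearman-Brown relation for the
#' agreement form.
#'
#' @param ratings Numeric matrix, `n_targets >= 2` rows by `k_raters >= 2`
#'   columns, complete (no missing entries).
#' @param type `"agreement"` (absolute agreement, the stricter standard)
#'   or `"consistency"`.
#' @param conf_level Confidence level for the interval.
#' @return An object of class `"icc_result"`: a list with `icc`, `ci_low`,
#'   `ci_high`, `model`, `type`, `n`, `k`, mean squares (`msr`, `msc`,
#'   `mse`) and `excellent` (`icc > 0.7`).
#' @examples
#' r <- cbind(c(10, 12.5, 11.2, 14.8, 13.1, 15.4),
#'            c(10.4, 12.1, 11.9, 14.2, 13.8, 15.9))
#' icc_twoway(r)
#' @export
icc_twoway <- function(ratings, type = c("agreement", "consistency"),
                       conf_level = 0.95) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  if (any(!is.finite(ratings))) {
    stop("missing data: the ratings matrix must be complete", call. = FALSE)
  }
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) {
    stop("need at least 2 targets and 2 raters", call. = FALSE)
  }
  grand <- mean(ratings)
  rowm <- rowMeans(ratings); colm <- colMeans(ratings)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  alpha <- 1 - conf_level
  if (mse <= .Machine$double.eps * max(sst, 1) && msc <= mse) {
    # identical raters: perfect agreement, degenerate F intervals
    icc <- if (msr > 0) 1 else NA_real_
    lo <- hi <- icc
  } else if (type == "consistency") {
    icc <- (msr - mse) / msr
    f <- msr / mse
    fl <- f / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo <- 1 - 1 / fl
    hi <- 1 - 1 / fu
  } else {
    icc <- (msr - mse) / (msr + (msc - mse) / n)
    # single-measure ICC(A,1) interval, Spearman-Brown mapped to k measures
    icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    fj <- msc / mse
    cc <- k * icc1
    dd <- n * (1 + (k - 1) * icc1) - k * icc1
    v <- (k - 1) * (n - 1) * (cc * fj + dd)^2 /
      ((n - 1) * cc^2 * fj^2 + dd^2)
    f3u <- stats::qf(1 - alpha / 2, n - 1, v)
    f3l <- stats::qf(1 - alpha / 2, v, n - 1)
    lo1 <- n * (msr - f3u * mse) /
      (f3u * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi1 <- n * (f3l * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f3l * msr)
    lo <- lo1 * k / (1 + (k - 1) * lo1)
    hi <- hi1 * k / (1 + (k - 1) * hi1)
  }
  structure(
    list(icc = icc, ci_low = min(lo, icc), ci_high = max(hi, icc),
         model = "two_way_random_average", type = type,
         conf_level = conf_level, n = n, k = k,
         msr = msr, msc = msc, mse = mse,
         excellent = isTRUE(icc > 0.7)),
    class = "icc_result"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s, k = %d raters, n = %d targets): %.3f (%.0f%% CI %.3f–%.3f)\n",
              if (x$type == "agreement") "A" else "C", x$k, x$n, x$icc,
              100 * x$conf_level, x$ci_low, x$ci_high))
  cat(if (x$excellent) "  excellent agreement (ICC > 0.7)\n" else
    "  below the excellent-agreement threshold (0.7)\n")
  invisible(x)
}

#' Group-comparison table across variables
#'
#' Applies [compare_groups()] to each listed variable of a subject-level
#' table, mirroring the cohort-characteristics layout: one row per
#' variable with branch-appropriate summaries and the p-value.
#'
#' @param data A `data.frame` with one row per subject.
#' @param vars Character vector of numeric column names to compare.
#' @param group Name of the two-level grouping column.
#' @param alpha Shapiro-Wilk gate level.
#' @return A `data.frame` with columns `variable`, the two group-summary
#'   columns (named by group level), `test`, `p_value`, and the per-group
#'   Shapiro-Wilk p-values.
#' @export
group_comparison_table <- function(data, vars, group, alpha = 0.05) {
  g <- data[[group]]
  lev <- unique(g)
  if (length(lev) != 2) stop("'group' must have exactly 2 levels",
                             call. = FALSE)
  rows <- lapply(vars, function(v) {
    cmp <- tryCatch(
      compare_groups(data[[v]][g == lev[1]], data[[v]][g == lev[2]],
                     alpha = alpha, variable = v, group_names = lev),
      error = function(e) NULL)
    if (is.null(cmp)) {
      # variable not comparable (e.g. too few finite values in a group)
      cmp <- list(summary = c(NA_character_, NA_character_),
                  test_used = NA_character_, p_value = NA_real_,
                  normality_p = c(NA_real_, NA_real_))
    }
    stats::setNames(
      data.frame(v, cmp$summary[1], cmp$summary[2], cmp$test_used,
                 cmp$p_value, cmp$normality_p[1], cmp$normality_p[2],
                 stringsAsFactors = FALSE),
      c("variable", paste0("summary_", lev), "test", "p_value",
        paste0("shapiro_p_", lev)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Univariate regression table across responses and predictors
#'
#' One [univariate_regression()] row per response x predictor pair,
#' mirroring the association-table layout (n, standardized beta, raw
#' slope and SE, R-squared, adjusted r-squared, p).
#'
#' @param data A `data.frame` with one row per subject.
#' @param responses,predictors Character vectors of column names.
#' @return A `data.frame` with one row per pair.
#' @export
regression_table <- function(data, responses, predictors) {
  rows <- list()
  for (resp in responses) {
    for (pred in predictors) {
      fit <- tryCatch(univariate_regression(data[[resp]], data[[pred]]),
                      error = function(e) NULL)
      if (is.null(fit)) next
      rows[[length(rows) + 1]] <- data.frame(
        response = resp, predictor = pred, n = fit$n,
        beta_std = fit$beta_std, slope_raw = fit$slope_raw,
        slope_se = fit$slope_se, r2 = fit$r2, adj_r2 = fit$adj_r2,
        p_value = fit$p_value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
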