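# Independent oracles used across test files. These deliberately avoid the
# package's fitting code paths.

PAPER_TI <- c(90, 240, 756, 923, 1440, 2106, 2790)

# Exhaustive lattice search for the best 3-parameter fit (including all
# polarity candidates for magnitude data), using the closed-form expansion
# rss(A, B) = n A^2 + B^2 See + Syy - 2AB Se - 2A Sy + 2B Sey so the grid
# is cheap. Returns the minimum RSS over the lattice.
oracle_grid_rss <- function(signal, ti, truth, span = 0.5, n_grid = 50,
                            magnitude = TRUE) {
  As <- seq(truth[1] * (1 - span), truth[1] * (1 + span),
            length.out = n_grid)
  Bs <- seq(truth[2] * (1 - span), truth[2] * (1 + span),
            length.out = n_grid)
  T1s <- seq(truth[3] * (1 - span), truth[3] * (1 + span),
             length.out = n_grid)
  T1s <- T1s[T1s > 0]
  cands <- if (magnitude) restore_polarity(signal) else list(signal)
  n <- length(ti)
  A2 <- outer(As^2, rep(1, length(Bs)))
  Amat <- outer(As, rep(1, length(Bs)))
  Bmat <- outer(rep(1, length(As)), Bs)
  B2 <- Bmat^2
  AB <- Amat * Bmat
  best <- Inf
  for (T1 in T1s) {
    e <- exp(-ti / T1)
    See <- sum(e^2); Se <- sum(e)
    for (y in cands) {
      Syy <- sum(y^2); Sy <- sum(y); Sey <- sum(e * y)
      rss <- n * A2 + B2 * See + Syy - 2 * AB * Se - 2 * Amat * Sy +
        2 * Bmat * Sey
      m <- min(rss)
      if (m < best) best <- m
    }
  }
  best
}

# Brute-force ROI metrics by scanning voxels one by one.
oracle_roi_scan <- function(t1, mask) {
  vals <- c()
  for (i in seq_len(nrow(t1))) {
    for (j in seq_len(ncol(t1))) {
      if (mask[i, j] && is.finite(t1[i, j])) vals <- c(vals, t1[i, j])
    }
  }
  list(peak = max(vals), mean = mean(vals), min = min(vals),
       n = length(vals))
}

# Closed-form OLS on a handful of points via the normal equations.
oracle_ols <- function(y, x) {
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b <- sxy / sxx
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  tval <- b / se
  list(slope = b, se = se, r2 = r2,
       p = 2 * stats::pt(-abs(tval), n - 2),
       beta_std = b * stats::sd(x) / stats::sd(y))
}

# Two-way ANOVA mean squares by direct arithmetic (targets x raters).
oracle_anova_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ssr <- k * sum((rowMeans(m) - grand)^2)
  ssc <- n * sum((colMeans(m) - grand)^2)
  sse <- sum((m - grand)^2) - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

# ICC(A,k) from the mean squares, written out independently.
oracle_icc_ak <- function(m) {
  ms <- oracle_anova_ms(m)
  (ms$msr - ms$mse) / (ms$msr + (ms$msc - ms$mse) / ms$n)
}

# Fixed two-sample fixtures with reference values frozen from independent
# implementations (scipy.stats 1.17.1 / pingouin 0.6.1).
fixture_groups <- function() {
  list(
    a = c(12.1, 14.3, 11.8, 13.5, 12.9, 15.2, 13.1, 12.4),
    b = c(13.9, 15.1, 14.8, 16.0, 15.5, 14.2, 16.3, 15.0),
    t_stat = -3.8807213516315056,
    t_p = 0.0016637204707707237,
    mww_p = 0.006993006993006993
  )
}

fixture_icc <- function() {
  list(
    ratings = cbind(c(10.0, 12.5, 11.2, 14.8, 13.1, 15.4),
                    c(10.4, 12.1, 11.9, 14.2, 13.8, 15.9)),
    icc_ak = 0.97998197329532355,
    icc_ck = 0.97953026461899473,
    ci_ak = c(0.88, 1.00)   # reference CI reported to 2 dp
  )
}

fixture_ols <- function() {
  list(x = c(1, 2, 3, 4, 5), y = c(2.1, 3.9, 6.2, 7.8, 10.1),
       slope = 1.99, se = 0.059721576223897795,
       r2 = 0.99730532890097701, p = 5.9415391117559292e-05)
}
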