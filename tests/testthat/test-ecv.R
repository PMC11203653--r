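test_that("ECV closed form matches direct arithmetic and its limits", {
  # zero numerator: equal muscle T1 pre/post
  expect_equal(compute_ecv(1500, 1500, 1700, 400, 0.4), 0)
  # pure-blood limit: hct -> 0 and equal relaxivity changes
  expect_equal(compute_ecv(1700, 400, 1700, 400, 1e-12), 1,
               tolerance = 1e-9)
  # worked scalar example
  expect_equal(compute_ecv(1900, 600, 1700, 400, 0.40),
               0.6 * (1 / 600 - 1 / 1900) / (1 / 400 - 1 / 1700),
               tolerance = 1e-14)
})

test_that("ECV equals scalar arithmetic on many random valid inputs", {
  set.seed(41)
  n <- 1000
  t1m_pre <- runif(n, 1400, 2200)
  t1m_post <- runif(n, 300, 900)
  t1b_pre <- runif(n, 1500, 2000)
  t1b_post <- runif(n, 250, 500)
  hct <- runif(n, 0.25, 0.55)
  # a few random draws legitimately land above 1 and trip the
  # implausibility warning; the check here is the arithmetic
  got <- suppressWarnings(compute_ecv(t1m_pre, t1m_post, t1b_pre,
                                      t1b_post, hct))
  ref <- (1 - hct) * (1 / t1m_post - 1 / t1m_pre) /
    (1 / t1b_post - 1 / t1b_pre)
  expect_equal(as.numeric(got), ref, tolerance = 1e-12)
})

test_that("ECV is strictly decreasing in hematocrit", {
  hcts <- seq(0.05, 0.95, by = 0.05)
  vals <- vapply(hcts, function(h) compute_ecv(1900, 600, 1700, 400, h),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("ECV is invariant to the T1 unit (seconds vs milliseconds)", {
  ms <- compute_ecv(1900, 600, 1700, 400, 0.4)
  s <- compute_ecv(1.9, 0.6, 1.7, 0.4, 0.4)
  expect_equal(ms, s, tolerance = 1e-12)
})

test_that("hematocrit in percent is auto-detected; invalid inputs error", {
  expect_message(pct <- compute_ecv(1900, 600, 1700, 400, 40),
                 "percent")
  expect_equal(pct, compute_ecv(1900, 600, 1700, 400, 0.40))
  expect_error(compute_ecv(1900, 600, 1700, 1700, 0.4),
               "division by zero")
  expect_error(suppressMessages(compute_ecv(1900, 600, 1700, 400, 150)),
               "hematocrit")
  expect_error(compute_ecv(1900, 600, 1700, 400, 0), "hematocrit")
  expect_error(compute_ecv(-1900, 600, 1700, 400, 0.4), "positive")
})

test_that("implausible ECV values are flagged, not clamped", {
  # post > pre muscle: negative numerator (also warns about the reversed
  # contrast direction)
  warns <- capture_warnings(bad <- compute_ecv(1500, 1600, 1700, 400, 0.4))
  expect_match(warns, "outside", all = FALSE)
  expect_match(warns, "shorten", all = FALSE)
  expect_lt(as.numeric(bad), 0)
  expect_true(attr(bad, "implausible"))
})

test_that("cohort ECV joins tables and counts exclusions", {
  mk_metrics <- function(subjects, peak) {
    do.call(rbind, lapply(subjects, function(s) {
      data.frame(subject = s, group = "pad",
                 compartment = c("AM", "LM", "DM", "SM", "GM"),
                 peak_t1_ms = peak, mean_t1_ms = peak - 400,
                 min_t1_ms = peak - 800, csa_mm2 = 500,
                 stringsAsFactors = FALSE)
    }))
  }
  pre <- mk_metrics(c("s1", "s2", "s3"), 1900)
  post <- mk_metrics(c("s1", "s2", "s3"), 650)
  subjects <- data.frame(subject = c("s1", "s2", "s3"),
                         hematocrit = c(0.4, NA, 0.45),
                         t1b_pre_ms = 1700, t1b_post_ms = 380,
                         stringsAsFactors = FALSE)
  out <- cohort_ecv(pre, post, subjects)
  expect_equal(nrow(out), 2 * 5)
  expect_equal(attr(out, "n_excluded"), 1)
  expect_equal(attr(out, "excluded_subjects"), "s2")
  expect_false("s2" %in% out$subject)
  # all complete: rows = subjects x 5, no exclusions
  subjects$hematocrit[2] <- 0.42
  out2 <- cohort_ecv(pre, post, subjects)
  expect_equal(nrow(out2), 3 * 5)
  expect_equal(attr(out2, "n_excluded"), 0)
  # hand-check one value
  expect_equal(out2$ecv_pct[out2$subject == "s1" &
                              out2$compartment == "AM"],
               100 * 0.6 * (1 / 650 - 1 / 1900) / (1 / 380 - 1 / 1700),
               tolerance = 1e-12)
})

test_that("noiseless pipeline ECV equals generator ground truth", {
  cfg <- cohort_config(n_pad = 2, n_control = 2, dims = c(32, 32),
                       noise_sigma = 0, noise_model = "none", seed = 13)
  coh <- generate_cohort(cfg)
  res <- analyze_cohort(coh)
  m <- merge(res$ecv, coh$truth, by = c("subject", "compartment"))
  expect_gt(nrow(m), 0)
  expect_equal(m$ecv_pct.x, m$ecv_pct.y, tolerance = 1e-6)
})
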