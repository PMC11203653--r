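test_that("noiseless phantom signals satisfy the signal model exactly", {
  cfg <- phantom_config(dims = c(32, 32), noise_sigma = 0,
                        noise_model = "none", seed = 2)
  ph <- generate_phantom(cfg)
  for (nm in c("AM", "SM", "AT")) {
    m <- ph$regions$labels[[nm]]
    expected <- ir_signal(cfg$ti_list_ms, cfg$region_A[[nm]],
                          cfg$inv_efficiency * cfg$region_A[[nm]],
                          cfg$region_t1_pre[[nm]], magnitude = TRUE)
    for (k in seq_along(cfg$ti_list_ms)) {
      frame <- ph$pre$frames[, , k]
      expect_equal(max(abs(frame[m] - expected[k])), 0)
    }
  }
})

test_that("phantom generation is seed-deterministic", {
  cfg <- phantom_config(dims = c(32, 32), noise_sigma = 10, seed = 9)
  p1 <- generate_phantom(cfg)
  p2 <- generate_phantom(cfg)
  expect_identical(p1$pre$frames, p2$pre$frames)
  expect_identical(p1$post$frames, p2$post$frames)
  # and different under another seed
  cfg2 <- phantom_config(dims = c(32, 32), noise_sigma = 10, seed = 10)
  expect_false(identical(generate_phantom(cfg2)$pre$frames, p1$pre$frames))
})

test_that("region masks are pairwise disjoint and lie inside the leg", {
  regs <- calf_region_masks(c(64, 64))
  nms <- c("AM", "LM", "DM", "SM", "GM", "AT", "PT", "PE")
  for (i in seq_along(nms)) {
    for (j in seq_along(nms)) {
      if (i < j) {
        expect_equal(sum(regs$labels[[nms[i]]] & regs$labels[[nms[j]]]), 0)
      }
    }
  }
  for (nm in nms) {
    expect_true(all(regs$labels$leg[regs$labels[[nm]]]))
    expect_gt(sum(regs$labels[[nm]]), 0)
  }
})

test_that("Rician background mean matches the closed-form Rayleigh mean", {
  # with A = 0 the magnitude signal is Rayleigh: mean sigma * sqrt(pi/2)
  sigma <- 5
  cfg <- phantom_config(dims = c(128, 256), noise_sigma = sigma,
                        noise_model = "rician", seed = 12)
  ph <- generate_phantom(cfg)
  background <- !ph$regions$labels$leg
  expect_gt(sum(background), 1e4)
  vals <- ph$pre$frames[, , 1][background]
  expected <- sigma * sqrt(pi / 2)
  se <- sigma * sqrt(2 - pi / 2) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - expected), 3 * se)
})

test_that("Gaussian noise preserves the noiseless mean signal", {
  sigma <- 15
  cfg0 <- phantom_config(dims = c(64, 64), noise_sigma = 0,
                         noise_model = "none", seed = 4)
  cfg <- phantom_config(dims = c(64, 64), noise_sigma = sigma,
                        noise_model = "gaussian", seed = 4)
  truth <- generate_phantom(cfg0)
  noisy <- generate_phantom(cfg)
  m <- noisy$regions$labels$SM
  # signed frames: noise should average out to 0 within 3 SE
  for (k in c(1, 4, 7)) {
    signed_truth <- ir_signal(cfg$ti_list_ms[k], cfg$region_A[["SM"]],
                              cfg$inv_efficiency * cfg$region_A[["SM"]],
                              cfg$region_t1_pre[["SM"]])
    dev <- mean(noisy$pre$frames[, , k][m]) - signed_truth
    expect_lt(abs(dev), 3 * sigma / sqrt(sum(m)))
  }
})

test_that("phantom configuration enforces its invariants", {
  expect_error(phantom_config(region_t1_post = c(AM = 2000, LM = 640,
                                                 DM = 650, SM = 645,
                                                 GM = 655, AT = 350,
                                                 PT = 350, PE = 350)),
               "post-contrast")
  expect_error(phantom_config(ti_list_ms = c(90, 240, 240, 923)),
               "strictly increasing")
  expect_error(phantom_config(inv_efficiency = 2.5))
  expect_error(phantom_config(noise_sigma = -1))
  bad_t1 <- c(AM = -5, LM = 1907, DM = 1917, SM = 1930, GM = 1945,
              AT = 1700, PT = 1700, PE = 1700)
  expect_error(phantom_config(region_t1_pre = bad_t1), "positive")
})
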