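test_that("compartment metrics: uniform map collapses to one value", {
  t1 <- matrix(1200, 10, 10)
  mask <- matrix(FALSE, 10, 10); mask[3:6, 3:6] <- TRUE
  m <- compartment_metrics(t1, mask, pixel_spacing_mm = 1)
  expect_equal(m$peak_t1_ms, 1200)
  expect_equal(m$mean_t1_ms, 1200)
  expect_equal(m$min_t1_ms, 1200)
  expect_equal(m$n_voxels, 16)
})

test_that("cross-sectional area is voxel count times pixel area", {
  mask <- matrix(FALSE, 30, 30)
  mask[seq_len(454)] <- TRUE
  t1 <- matrix(1500, 30, 30)
  m <- compartment_metrics(t1, mask, pixel_spacing_mm = 1)
  expect_equal(m$csa_mm2, 454)   # the lateral-compartment area scale
  m2 <- compartment_metrics(t1, mask, pixel_spacing_mm = 1.48)
  expect_equal(m2$csa_mm2, 454 * 1.48^2)
})

test_that("metrics equal a brute-force voxel scan on a random map", {
  set.seed(17)
  t1 <- matrix(runif(400, 800, 2200), 20, 20)
  t1[sample(400, 40)] <- NA   # invalid voxels
  mask <- matrix(runif(400) < 0.4, 20, 20)
  ref <- oracle_roi_scan(t1, mask)
  m <- compartment_metrics(t1, mask, pixel_spacing_mm = c(1.48, 1.48))
  expect_equal(m$peak_t1_ms, ref$peak)
  expect_equal(m$mean_t1_ms, ref$mean)
  expect_equal(m$min_t1_ms, ref$min)
  expect_equal(m$n_voxels, ref$n)
  expect_equal(m$csa_mm2, ref$n * 1.48^2)
})

test_that("adding an invalid voxel to a mask changes no metric", {
  set.seed(18)
  t1 <- matrix(runif(100, 800, 2200), 10, 10)
  t1[5, 5] <- NA
  mask <- matrix(FALSE, 10, 10); mask[2:4, 2:4] <- TRUE
  m1 <- compartment_metrics(t1, mask, 1)
  mask2 <- mask; mask2[5, 5] <- TRUE
  m2 <- compartment_metrics(t1, mask2, 1)
  expect_identical(unclass(m1), unclass(m2))
})

test_that("metrics are invariant under joint translation of map and mask", {
  set.seed(19)
  t1 <- matrix(NA_real_, 20, 20)
  t1[5:10, 5:10] <- runif(36, 800, 2200)
  mask <- matrix(FALSE, 20, 20); mask[5:10, 5:10] <- TRUE
  shift <- function(m, dx, dy) {
    out <- matrix(if (is.logical(m)) FALSE else NA_real_, 20, 20)
    out[(1 + dx):20, (1 + dy):20] <- m[1:(20 - dx), 1:(20 - dy)]
    out
  }
  m1 <- compartment_metrics(t1, mask, 1)
  m2 <- compartment_metrics(shift(t1, 6, 4), shift(mask, 6, 4), 1)
  expect_equal(unclass(m1), unclass(m2))
})

test_that("empty or all-invalid regions raise an empty-region error", {
  t1 <- matrix(NA_real_, 5, 5)
  mask <- matrix(TRUE, 5, 5)
  expect_error(compartment_metrics(t1, mask, 1), "empty region")
  expect_error(compartment_metrics(matrix(1, 5, 5), matrix(FALSE, 5, 5), 1),
               "empty region")
})

test_that("average peak T1 needs all five compartments and averages them", {
  mk <- function(p) structure(list(peak_t1_ms = p, mean_t1_ms = p,
                                   min_t1_ms = p, csa_mm2 = 1, n_voxels = 1),
                              class = "compartment_metrics")
  same <- lapply(c(AM = 1900, LM = 1900, DM = 1900, SM = 1900, GM = 1900),
                 mk)
  expect_equal(average_peak_t1(same), 1900)
  peaks <- c(AM = 1835.5, LM = 1907, DM = 1917.5, SM = 1930, GM = 1945.5)
  expect_equal(average_peak_t1(lapply(peaks, mk)),
               (1835.5 + 1907 + 1917.5 + 1930 + 1945.5) / 5)
  # permutation invariance
  expect_equal(average_peak_t1(lapply(peaks[c(3, 5, 1, 4, 2)], mk)),
               average_peak_t1(lapply(peaks, mk)))
  expect_error(average_peak_t1(lapply(peaks[1:4], mk)), "incomplete set")
})

test_that("blood-pool T1 averages per-artery peaks and tolerates missing arteries", {
  t1 <- matrix(NA_real_, 12, 12)
  mk_mask <- function(rows, cols) {
    m <- matrix(FALSE, 12, 12); m[rows, cols] <- TRUE; m
  }
  labs <- list(AT = mk_mask(1:2, 1:2), PT = mk_mask(5:6, 5:6),
               PE = mk_mask(9:10, 9:10))
  t1[labs$AT] <- c(1500, 1600, 1550, 1400)
  t1[labs$PT] <- c(1650, 1700, 1680, 1690)
  t1[labs$PE] <- c(1750, 1800, 1790, 1600)
  regs <- region_set(labs, 1)
  b <- blood_pool_t1(t1, regs)
  expect_equal(as.numeric(b), mean(c(1600, 1700, 1800)))
  expect_equal(attr(b, "n_arteries"), 3)
  # one artery entirely invalid: mean of the remaining two, with a warning
  t1[labs$PE] <- NA
  expect_warning(b2 <- blood_pool_t1(t1, regs), "no valid voxels")
  expect_equal(as.numeric(b2), mean(c(1600, 1700)))
  expect_equal(attr(b2, "n_arteries"), 2)
  t1[labs$AT] <- NA; t1[labs$PT] <- NA
  expect_error(suppressWarnings(blood_pool_t1(t1, regs)), "empty region")
})

test_that("bilateral averaging is element-wise and label-checked", {
  mk <- function(peak, mean_, min_, csa, n, cmp = NULL) {
    structure(list(peak_t1_ms = peak, mean_t1_ms = mean_, min_t1_ms = min_,
                   csa_mm2 = csa, n_voxels = n),
              class = "compartment_metrics", compartment = cmp)
  }
  left <- mk(1800, 1300, 900, 800, 400, "AM")
  right <- mk(1900, 1350, 880, 1000, 500, "AM")
  avg <- bilateral_average(left, right)
  expect_equal(avg$peak_t1_ms, 1850)
  expect_equal(avg$csa_mm2, 900)
  expect_equal(avg$n_voxels, 450)
  # identical sides unchanged
  expect_equal(unclass(bilateral_average(left, left)), unclass(left))
  expect_error(bilateral_average(left, mk(1, 1, 1, 1, 1, "SM")),
               "label error")
})

test_that("muscle metrics table has the frozen schema", {
  ph <- generate_phantom(phantom_config(dims = c(32, 32), noise_sigma = 0,
                                        noise_model = "none", seed = 3))
  map <- fit_t1_map(ph$pre, mask = region_union(ph$regions))
  tab <- muscle_metrics_table(map, ph$regions, subject = "s1",
                              group = "pad")
  expect_named(tab, c("subject", "group", "compartment", "peak_t1_ms",
                      "mean_t1_ms", "min_t1_ms", "csa_mm2"))
  expect_setequal(tab$compartment, c("AM", "LM", "DM", "SM", "GM"))
  # noiseless uniform regions: peak == mean == min == configured T1
  for (i in seq_len(nrow(tab))) {
    cmp <- tab$compartment[i]
    expect_equal(tab$peak_t1_ms[i], ph$truth$region_t1_pre[[cmp]],
                 tolerance = 1e-6)
    expect_equal(tab$min_t1_ms[i], tab$peak_t1_ms[i], tolerance = 1e-6)
  }
})
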