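test_that("sliding mean window matches the worked example and limits", {
  expect_equal(sliding_mean_window(1:7, 2), c(2, 2.5, 3, 4, 5, 5.5, 6))
  expect_equal(sliding_mean_window(rep(3.2, 9), 2), rep(3.2, 9))
  x <- rnorm(15)
  expect_equal(sliding_mean_window(x, 0), x)
  expect_error(sliding_mean_window(numeric(0)), "non-empty")
  expect_error(sliding_mean_window(1:3, -1), "non-negative")
})

test_that("sliding mean window equals brute force incl. missing handling", {
  set.seed(100)
  for (rep in 1:25) {
    n <- sample(1:40, 1)
    x <- rnorm(n)
    x[sample(n, floor(n / 4))] <- NA
    for (h in 0:5)
      expect_equal(sliding_mean_window(x, h), oracle_sliding_mean(x, h))
  }
  expect_true(is.na(sliding_mean_window(c(NA, NA, 1), 0)[1]))
})

test_that("streamline sampling is exact on constant fields and midpoints", {
  vol <- array(0.7, dim = c(4, 4, 4))
  pts <- cbind(c(0.3, 1.1, 2.9), c(0.5, 1.5, 2.5), c(0, 1, 2))
  for (mode in c("nearest", "trilinear")) {
    s <- sample_along_streamline(vol, c(1, 1, 1), pts, mode)
    expect_equal(s$values, rep(0.7, 3))
  }
  s <- sample_along_streamline(vol, c(1, 1, 1), pts)
  seg <- sqrt(rowSums((pts[-1, ] - pts[-3, ])^2))
  expect_equal(s$arc_mm, c(0, cumsum(seg)))

  # trilinear midpoint between voxel values 0 and 1
  vol2 <- array(c(0, 1), dim = c(2, 1, 1))
  mid <- sample_along_streamline(vol2, c(2, 2, 2), cbind(1, 0, 0), "trilinear")
  expect_equal(mid$values, 0.5)

  expect_error(sample_along_streamline(vol, c(1, 1, 1), cbind(10, 0, 0)),
               "point 1")
})

test_that("tract profiles recover programmed phantom values exactly", {
  ph <- simulate_cord_phantom(seed = 2)
  pr <- extract_phantom_profiles(ph, smooth_half_width = 0)
  expect_equal(unique(pr$lateral_CST$values), 0.55)
  expect_equal(unique(pr$posterior_column$values), 0.60)
  expect_equal(unique(pr$spinal_lemniscus$values), 0.50)
  # smoothing a constant profile changes nothing
  pr2 <- extract_phantom_profiles(ph, smooth_half_width = 2)
  expect_equal(pr2$lateral_CST$values, pr$lateral_CST$values)
})

test_that("impossible confidence threshold errors with the tract name", {
  ph <- simulate_cord_phantom(seed = 2)
  samples <- streamline_samples(ph$metric_volumes$FA, ph$voxel_dims_mm,
                                ph$streamlines)
  grid <- cord_grid(points_per_level = 6, spacing_mm = 3.3)
  expect_error(tract_profile(samples, ph$tract_maps[[1]], ph$voxel_dims_mm,
                             grid, threshold = 1.1, tract = "lateral_CST"),
               "lateral_CST")
})

test_that("left/right averaging is a mean of per-side means", {
  grid <- cord_grid(levels = "C2", points_per_level = 3, spacing_mm = 1)
  vol <- array(1, dim = c(3, 3, 3))  # confidence map: everything survives
  mk <- function(val, side, n) {
    lapply(seq_len(n), function(i) list(
      points = cbind(1, 1, 0:2), arc_mm = 0:2, values = rep(val, 3),
      tract = "t", side = side))
  }
  # 3 left streamlines at 0.50, 1 right at 0.60: pooled mean would be 0.525
  samples <- c(mk(0.5, "left", 3), mk(0.6, "right", 1))
  class(samples) <- "streamline_samples"
  p <- tract_profile(samples, vol, c(1, 1, 1), grid, lr_average = TRUE)
  expect_equal(p$values, rep(0.55, 3))
  p2 <- tract_profile(samples, vol, c(1, 1, 1), grid, lr_average = FALSE)
  expect_equal(p2$values, rep(0.525, 3))
})

test_that("CSA is count x in-plane voxel area and behaves geometrically", {
  grid <- cord_grid(levels = "C2", points_per_level = 2, spacing_mm = 3.3)
  mask <- array(0, dim = c(10, 10, 2))
  mask[1:10, 1:5, 1] <- 1   # 50 voxels
  mask[3:10, 3:7, 2] <- 1   # translated/shaped differently: 40 voxels
  p <- cord_csa_profile(mask, c(1.12, 1.12, 3.3), c("C2", "C2"), grid)
  expect_equal(p$values, c(50, 40) * 1.2544)

  # translation invariance
  mask2 <- array(0, dim = c(10, 10, 2))
  mask2[1:10, 6:10, 1] <- 1
  mask2[1:8, 1:5, 2] <- 1
  p2 <- cord_csa_profile(mask2, c(1.12, 1.12, 3.3), c("C2", "C2"), grid)
  expect_equal(p2$values, p$values)

  # linear scaling with voxel area
  p3 <- cord_csa_profile(mask, c(2.24, 1.12, 3.3), c("C2", "C2"), grid)
  expect_equal(p3$values, 2 * p$values)

  # empty slice: CSA 0 with a warning
  mask[, , 2] <- 0
  expect_warning(p4 <- cord_csa_profile(mask, c(1.12, 1.12, 3.3),
                                        c("C2", "C2"), grid), "empty")
  expect_equal(p4$values[2], 0)

  # phantom cylinder: constant CSA equal to voxel count x area
  ph <- simulate_cord_phantom(seed = 1)
  pr <- extract_phantom_profiles(ph, smooth_half_width = 0)
  counts <- apply(ph$cord_mask, 3, sum)
  expect_true(all(counts == counts[1]))
  expect_equal(unique(pr$CSA$values), counts[1] * 1.12 * 1.12)
})

test_that("level alignment resamples linearly within levels", {
  grid <- cord_grid(levels = c("C2", "C3"), points_per_level = 4,
                    spacing_mm = 1)
  # native grid identical to canonical: identity
  native <- rep(c("C2", "C3"), each = 4)
  vals <- rnorm(8)
  p <- level_align(vals, native, grid)
  expect_equal(p$values, vals)

  # 2:1 downsampling of a linear ramp stays on the line
  native8 <- rep(c("C2", "C3"), each = 8)
  ramp <- seq(0, 30, length.out = 16)
  p2 <- level_align(ramp, native8, grid)
  for (lv in c("C2", "C3")) {
    gi <- which(grid$levels == lv)
    si <- which(native8 == lv)
    expect_equal(p2$values[gi],
                 approx(seq(0, 1, length.out = 8), ramp[si],
                        seq(0, 1, length.out = 4))$y)
  }

  expect_error(level_align(vals[1:4], rep("C2", 4), grid), "C3")
  expect_warning(level_align(c(vals[1:4], 9), c(native[1:4], "C3"), grid),
                 "single native sample")
})

test_that("change profiles subtract position-wise with missing propagation", {
  grid <- quick_grid()
  mk <- function(v) cordvcm:::new_metric_profile("s1", "lateral_CST", "RD",
                                                 grid, v)
  base <- mk(seq(0.4, 0.6, length.out = 50))
  expect_equal(change_profile(base, base)$values, rep(0, 50))
  up <- mk(base$values * 1.1)
  expect_equal(change_profile(base, up)$values, 0.1 * base$values,
               tolerance = 1e-12)
  const <- change_profile(mk(rep(0.5, 50)), mk(rep(0.55, 50)))
  expect_equal(const$values, rep(0.05, 50), tolerance = 1e-12)
  withna <- mk(replace(base$values, 7, NA))
  expect_true(is.na(change_profile(base, withna)$values[7]))
  g2 <- cord_grid(points_per_level = 5)
  expect_error(change_profile(base, cordvcm:::new_metric_profile(
    "s1", "lateral_CST", "RD", g2, rep(0, 25))), "grid")
})

test_that("whole-cord profile is the count-weighted mix of disjoint tracts", {
  grid <- cord_grid(levels = "C2", points_per_level = 3, spacing_mm = 1)
  ones <- array(1, dim = c(3, 3, 3))
  mk <- function(val, n, tract) lapply(seq_len(n), function(i) list(
    points = cbind(1, 1, 0:2), arc_mm = 0:2, values = rep(val, 3),
    tract = tract, side = "midline"))
  sA <- mk(0.5, 3, "A"); sB <- mk(0.8, 1, "B")
  pool <- function(s) { class(s) <- "streamline_samples"; s }
  pA <- tract_profile(pool(sA), ones, c(1, 1, 1), grid, lr_average = FALSE)
  pB <- tract_profile(pool(sB), ones, c(1, 1, 1), grid, lr_average = FALSE)
  whole <- tract_profile(pool(c(sA, sB)), ones, c(1, 1, 1), grid,
                         lr_average = FALSE, tract = "whole_cord")
  expect_equal(whole$values, (3 * pA$values + 1 * pB$values) / 4)
})
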