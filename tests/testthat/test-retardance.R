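# Retardance estimation: profile arithmetic, slope fitting, map round trips,
# stitching geometry.

test_that("retardance profile reproduces the trivial channel configurations", {
  ny <- 2; nx <- 2; nz <- 8
  zero1 <- polarization_volume(array(0, c(ny, nx, nz)),
                               array(2, c(ny, nx, nz)))
  expect_equal(retardance_profile(zero1, 1, 1), rep(0, nz))
  eq <- polarization_volume(array(1.3, c(ny, nx, nz)),
                            array(1.3, c(ny, nx, nz)))
  expect_equal(retardance_profile(eq, 2, 2), rep(45, nz))
  both0 <- polarization_volume(array(0, c(ny, nx, nz)),
                               array(0, c(ny, nx, nz)))
  expect_true(all(is.na(retardance_profile(both0, 1, 2))))
  expect_error(retardance_profile(eq, 3, 1), "out of bounds")
})

test_that("forward model arithmetic: slope 0.5 deg/um at dz 3 um gives 15 deg at plane 10", {
  vol <- simulate_psoct_volume(matrix(0.5, 3, 3), depth_px = 20,
                               voxel_depth = 3)
  phi <- retardance_profile(vol, 2, 2)
  expect_equal(phi[11], 15)  # plane index 10 in 0-based depth
  expect_equal(phi, 0.5 * (0:19) * 3)
})

test_that("slope fitting is exact on linear input and clamps negative fits", {
  phi <- 0.4 * (0:29) * 3
  fit <- fit_slope(phi, dz = 3, skip_top = 0)
  expect_equal(fit[["slope"]], 0.4)
  expect_equal(fit[["r_squared"]], 1)
  expect_equal(fit_slope(rep(7, 30), dz = 3)[["slope"]], 0)
  declining <- 20 - 0.2 * (0:29) * 3
  expect_equal(fit_slope(declining, dz = 3)[["slope"]], 0)
  short <- c(1, 2, NA, NA)
  expect_true(is.na(fit_slope(short, dz = 3, skip_top = 0)[["slope"]]))
})

test_that("noisy slope estimates are unbiased within 3 SE (profile-level oracle)", {
  s <- 0.4; dz <- 3; n <- 50
  depths <- (0:(n - 1)) * dz
  est <- withr::with_seed(42, vapply(1:500, function(r) {
    phi <- s * depths + rnorm(n, sd = 2)
    fit_slope(phi, dz = dz, skip_top = 0)[["slope"]]
  }, numeric(1)))
  se <- sd(est) / sqrt(500)
  expect_lt(abs(mean(est) - s), 3 * se)
})

test_that("noiseless volume -> map round trip recovers the slope map exactly", {
  sm <- matrix(runif(12 * 10, 0.1, 0.7), 12, 10)
  vol <- simulate_psoct_volume(sm, depth_px = 30, voxel_depth = 3)
  rmap <- retardance_map(vol)
  expect_equal(rmap$slope, sm, tolerance = 1e-12)
  expect_equal(rmap$r_squared, matrix(1, 12, 10))
})

test_that("two-region slope maps segment at the boundary", {
  sm <- cbind(matrix(0.2, 20, 10), matrix(0.6, 20, 10))
  vol <- simulate_psoct_volume(sm, depth_px = 30, voxel_depth = 3)
  rmap <- retardance_map(vol)
  expect_equal(rmap$slope, sm, tolerance = 1e-10)
})

test_that("pure-noise volumes give near-zero slopes with low fit quality", {
  vol <- withr::with_seed(7, polarization_volume(
    array(rnorm(20 * 20 * 40, sd = 0.2), c(20, 20, 40)),
    array(rnorm(20 * 20 * 40, sd = 0.2), c(20, 20, 40))))
  rmap <- retardance_map(vol, skip_top = 0)
  expect_lt(median(rmap$r_squared), 0.3)
  expect_lt(median(abs(rmap$slope)), 0.5)
})

test_that("slope maps are invariant to global amplitude scaling", {
  sm <- matrix(c(0.2, 0.4, 0.5, 0.3), 2, 2)
  v1 <- simulate_psoct_volume(sm, 25, voxel_depth = 3, amplitude = 1)
  v5 <- simulate_psoct_volume(sm, 25, voxel_depth = 3, amplitude = 5)
  expect_equal(retardance_map(v1)$slope, retardance_map(v5)$slope,
               tolerance = 1e-12)
})

test_that("estimated ROI mean increases with true birefringence (noiseless)", {
  slopes <- c(0.1, 0.3, 0.5, 0.7)
  mask <- matrix(TRUE, 4, 4)
  means <- vapply(slopes, function(s) {
    vol <- simulate_psoct_volume(matrix(s, 4, 4), 25, voxel_depth = 3)
    roi_mean(retardance_map(vol), mask)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_equal(means, slopes, tolerance = 1e-10)
})

test_that("single-tile stitching is the identity and constants are conserved", {
  t1 <- matrix(runif(400), 20, 20)
  s1 <- stitch_tiles(list(t1), origins = rbind(c(0, 0)))
  expect_equal(s1$slope, t1)
  tiles <- replicate(4, matrix(0.37, 20, 20), simplify = FALSE)
  org <- rbind(c(0, 0), c(0, 17), c(17, 0), c(17, 17))
  s <- stitch_tiles(tiles, origins = org, overlap_fraction = 0.15)
  expect_equal(dim(s$slope), c(37, 37))
  expect_equal(s$slope, matrix(0.37, 37, 37), tolerance = 1e-12)
})

test_that("stitching never alters pixels outside overlap zones", {
  t1 <- matrix(runif(400), 20, 20); t2 <- matrix(runif(400), 20, 20)
  s <- stitch_tiles(list(t1, t2), origins = rbind(c(0, 0), c(0, 17)))
  expect_equal(s$slope[, 1:17], t1[, 1:17])   # t1-only region (cols 18-20 overlap)
  expect_equal(s$slope[, 21:37], t2[, 4:20])  # t2-only region
})

test_that("a 10x10 mosaic of 3 mm tiles at 15% overlap spans 25.95 mm", {
  tile_px <- 200; pitch_mm <- 3 / tile_px     # 200 px = 3 mm
  step <- round(tile_px * 0.85)               # 170 px
  origins <- as.matrix(expand.grid(y = (0:9) * step, x = (0:9) * step))
  tiles <- replicate(100, matrix(0.3, tile_px, tile_px), simplify = FALSE)
  s <- stitch_tiles(tiles, origins = origins)
  expect_equal(dim(s$slope), c(1730, 1730))
  expect_equal(dim(s$slope)[2] * pitch_mm, 25.95)
})

test_that("inconsistent tile origins are reported with the offending tile", {
  tiles <- list(matrix(1, 20, 20), matrix(1, 20, 20))
  expect_error(stitch_tiles(tiles, origins = rbind(c(0, 0), c(0, 11))),
               "tile 2")
})

test_that("roi_mean averages masked pixels and rejects empty masks", {
  m <- matrix(0, 5, 5); m[1, 1] <- 2; m[5, 5] <- 4
  mask <- matrix(FALSE, 5, 5); mask[1, 1] <- mask[5, 5] <- TRUE
  expect_equal(roi_mean(m, mask), 3)
  expect_equal(roi_mean(matrix(0.42, 5, 5), matrix(TRUE, 5, 5)), 0.42)
  expect_error(roi_mean(m, matrix(FALSE, 5, 5)), "empty")
})

test_that("low-R^2 pixels can be excluded from ROI means", {
  rmap <- structure(list(slope = matrix(c(1, 1, 5, 5), 2, 2),
                         r_squared = matrix(c(0.9, 0.9, 0.1, 0.1), 2, 2),
                         pixel_pitch = 10, tile_origin = c(0, 0)),
                    class = "retardance_map")
  expect_equal(roi_mean(rmap, matrix(TRUE, 2, 2)), 3)
  expect_equal(roi_mean(rmap, matrix(TRUE, 2, 2), min_r_squared = 0.5), 1)
})
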