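# File formats, fast-lifetime maps, exclusion rules and ROI pooling.

test_that("histogram CSV round-trips losslessly and rejects malformed input", {
  h <- simulate_histogram(ref_pattern(), 0.2, 0.4, 0.01, n_photons = 1e5,
                          seed = 41)
  path <- withr::local_tempfile(fileext = ".csv")
  write_histogram_csv(h, path)
  h2 <- read_histogram_csv(path)
  expect_equal(h2$counts, h$counts)
  expect_equal(h2$time_ns, h$time_ns, tolerance = 1e-12)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_ns,counts", "0,5", "0.05,-3", "0.1,2"), bad)
  expect_error(read_histogram_csv(bad), "negative.*line 3")

  writeLines(c("time_ns,counts", "0.00,5", "0.05,3", "0.11,2", "0.16,1"), bad)
  expect_error(read_histogram_csv(bad), "not uniform")

  writeLines(c("t,counts", "0,5"), bad)
  expect_error(read_histogram_csv(bad), "header")
})

test_that("time stacks round-trip through multi-page TIFF with sidecar metadata", {
  sc <- flim_scene(c(16L, 16L),
                   tibble::tibble(row = 8, col = 8, r_row = 5, r_col = 5,
                                  binding = 0, efficiency = 0, density = 10),
                   nucleolus_fraction = 0)
  sim <- simulate_flim_image(sc, ref_pattern(), grid = bin_grid(0.05, 250L),
                             seed = 42)
  path <- withr::local_tempfile(fileext = ".tif")
  write_time_stack_tiff(sim$image, path)
  img2 <- read_time_stack_tiff(path)
  expect_identical(unclass(img2), unclass(sim$image))
  g2 <- opaflim:::image_grid(img2)
  expect_equal(g2$bin_width_ns, 0.05)
  expect_equal(g2$n_bins, 250L)

  # sidecar removed: an explicit bin width is required
  file.remove(paste0(path, ".json"))
  expect_error(read_time_stack_tiff(path), "bin width")
  img3 <- read_time_stack_tiff(path, bin_width_ns = 0.05)
  expect_identical(unclass(img3), unclass(sim$image))

  # single-page stack is accepted with a warning
  one <- flim_image(array(1L, dim = c(4, 4, 1)), bin_grid(0.05, 1L))
  p1 <- withr::local_tempfile(fileext = ".tif")
  write_time_stack_tiff(one, p1)
  expect_warning(read_time_stack_tiff(p1), "single-page")

  # pixels that cannot be photon counts are rejected, not coerced
  pf <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(runif(16), 4, 4), pf, bits.per.sample = 32L)
  expect_error(suppressWarnings(read_time_stack_tiff(pf, bin_width_ns = 0.05)))
})

test_that("ROI masks with negative labels round-trip through TIFF", {
  m <- roi_mask(matrix(c(0L, 1L, -1L, 2L, -2L, 3L, 0L, 0L, 1L), 3, 3))
  path <- withr::local_tempfile(fileext = ".tif")
  write_roi_mask_tiff(m, path)
  m2 <- read_roi_mask_tiff(path)
  expect_identical(unclass(m2), unclass(m))
})

test_that("fast-lifetime map estimates per-pixel mean arrival", {
  # mono-exponential pixel: mean of the window-truncated exponential
  tau <- 2.0
  g <- bin_grid(0.05, 500L)  # 25 ns window
  mono <- donor_pattern(tau, 1.0)
  h <- simulate_histogram(mono, 0, n_photons = 1e5, seed = 51, grid = g)
  img <- flim_image(array(h$counts, dim = c(1, 1, g$n_bins)), g)
  flm <- fast_lifetime_map(img, origin_ns = 0)
  w <- opaflim:::grid_window_ns(g)
  truncated_mean <- tau - w * exp(-w / tau) / (1 - exp(-w / tau))
  expect_lt(abs(flm[1, 1] - truncated_mean) / truncated_mean, 0.03)
  expect_lt(abs(flm[1, 1] - tau) / tau, 0.03)

  # uniform background pixel sits at mid-window
  img_bg <- flim_image(array(10L, dim = c(1, 1, g$n_bins)), g)
  expect_equal(fast_lifetime_map(img_bg, origin_ns = 0)[1, 1], w / 2,
               tolerance = 1e-9)

  # zero-photon pixel is NA, not 0
  img0 <- flim_image(array(0L, dim = c(2, 2, 10)), bin_grid(0.05, 10L))
  expect_true(all(is.na(fast_lifetime_map(img0, origin_ns = 0))))
})

test_that("low-lifetime pixels are flipped to excluded labels", {
  sc <- flim_scene(
    c(30L, 30L),
    tibble::tibble(row = 15, col = 15, r_row = 10, r_col = 10,
                   binding = 0, efficiency = 0, density = 100),
    nucleolus_fraction = 0,
    plastids = tibble::tibble(row = 15, col = 15, radius = 2,
                              lifetime_ns = 0.4, density = 400))
  sim <- simulate_flim_image(sc, ref_pattern(), grid = ref_grid(), seed = 52)
  expect_message(
    m2 <- exclude_low_lifetime_pixels(sim$image, sim$mask, 1.0, origin_ns = 0),
    "excluded")
  expect_gt(sum(m2 < 0), 0)
  # the spot centre pixel must be excluded
  expect_lt(m2[15, 15], 0)
  # a clean image is left unchanged
  sc2 <- flim_scene(c(20L, 20L),
                    tibble::tibble(row = 10, col = 10, r_row = 6, r_col = 6,
                                   binding = 0, efficiency = 0, density = 100),
                    nucleolus_fraction = 0)
  sim2 <- simulate_flim_image(sc2, ref_pattern(), grid = ref_grid(), seed = 53)
  expect_message(m3 <- exclude_low_lifetime_pixels(sim2$image, sim2$mask, 1.0,
                                                   origin_ns = 0))
  expect_identical(unclass(m3), unclass(sim2$mask))
  expect_error(exclude_low_lifetime_pixels(sim2$image, sim2$mask, 0), "> 0")
})

test_that("ROI pooling is additive, order-invariant and respects exclusions", {
  g <- bin_grid(0.05, 10L)
  counts <- array(0L, dim = c(2, 2, 10))
  counts[1, 1, 3] <- 3L; counts[2, 1, 3] <- 5L
  counts[1, 2, 5] <- 7L   # excluded pixel
  img <- flim_image(counts, g)
  mask <- roi_mask(matrix(c(1L, 1L, -1L, 0L), 2, 2))
  pooled <- pool_roi(img, mask, 1)
  expect_equal(pooled$counts[3], 8L)
  expect_equal(total_photons(pooled), 8L)  # nucleolus photons omitted
  expect_error(pool_roi(img, mask, 9), "not present")
  expect_error(pool_roi(img, mask, -1), "positive")
})

test_that("pooled nucleolus carve-outs reduce the ROI photon total", {
  sc <- flim_scene(c(24L, 24L),
                   tibble::tibble(row = 12, col = 12, r_row = 8, r_col = 8,
                                  binding = 0, efficiency = 0, density = 30),
                   nucleolus_fraction = 0.4)
  sim <- simulate_flim_image(sc, ref_pattern(), grid = ref_grid(), seed = 54)
  pooled <- pool_roi(sim$image, sim$mask, 1)
  expect_equal(total_photons(pooled), sim$truth$n_photons_included[1])
  expect_lt(total_photons(pooled), sim$truth$n_photons_total[1])
})

test_that("pooled fast lifetime equals the photon-weighted mean of pixel values", {
  sc <- flim_scene(c(16L, 16L),
                   tibble::tibble(row = 8, col = 8, r_row = 5, r_col = 5,
                                  binding = 0, efficiency = 0, density = 50),
                   nucleolus_fraction = 0)
  sim <- simulate_flim_image(sc, ref_pattern(), grid = ref_grid(), seed = 55)
  flm <- fast_lifetime_map(sim$image, origin_ns = 0)
  pooled <- pool_roi(sim$image, sim$mask, 1)
  g <- ref_grid()
  pooled_flm <- sum(pooled$counts * opaflim:::grid_centers(g)) /
    total_photons(pooled)
  tot_px <- apply(unclass(sim$image), c(1, 2), sum)
  sel <- sim$mask == 1 & tot_px > 0
  weighted <- sum(flm[sel] * tot_px[sel]) / sum(tot_px[sel])
  expect_equal(pooled_flm, weighted, tolerance = 1e-9)
})
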