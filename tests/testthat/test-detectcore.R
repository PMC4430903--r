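test_that("adaptive threshold matches the robust closed form", {
  # values 1..9: median 5, MAD 2, threshold 5 + k * 1.4826 * 2
  m <- matrix(1:9, 3, 3)
  tm <- estimate_threshold(m, k = 2)
  expect_equal(tm$background_median, 5)
  expect_equal(tm$background_mad, 2)
  expect_equal(tm$threshold, 10.9304)
  expect_false(tm$degenerate)

  const <- estimate_threshold(matrix(7, 4, 4), k = 6)
  expect_equal(const$threshold, 7)
  expect_true(const$degenerate)

  # shift equivariance: adding c moves the threshold by exactly c
  shifted <- estimate_threshold(m + 13.5, k = 2)
  expect_equal(shifted$threshold, tm$threshold + 13.5)

  expect_error(estimate_threshold(matrix(numeric(0), 0, 0)),
               class = "ctcscan_config_error")
})

test_that("segmentation finds constructed disks with correct geometry", {
  pitch <- 0.65
  plane <- hard_disk_plane(100, cx = 40.0, cy = 60.0, radius_px = 8,
                           amp = 5000)
  tm <- estimate_threshold(plane, k = 6)
  masks <- segment_primary(plane, tm, pitch)
  expect_length(masks, 1)
  expect_lt(max(abs(masks[[1]]$centroid_px - c(40, 60))), 0.5)
  expect_lt(abs(masks[[1]]$area_um2 - pi * 8^2 * pitch^2) /
            (pi * 8^2 * pitch^2), 0.05)

  # blank plane: nothing above threshold
  expect_length(segment_primary(matrix(100, 50, 50),
                                estimate_threshold(matrix(100, 50, 50)),
                                pitch), 0)

  # two well-separated disks
  two <- hard_disk_plane(120, 30, 30, 8, 5000) +
    hard_disk_plane(120, 90, 90, 8, 5000)
  masks2 <- segment_primary(two, estimate_threshold(two, k = 6), pitch)
  expect_length(masks2, 2)
  # deterministic row-major order by bounding-box origin
  expect_lt(masks2[[1]]$bbox[1], masks2[[2]]$bbox[1])
})

test_that("segmentation is 8-connected and fills holes", {
  plane <- matrix(0, 20, 20)
  plane[5, 5] <- 100; plane[6, 6] <- 100; plane[7, 7] <- 100
  tm <- list(threshold = 50)
  masks <- segment_primary(plane, tm, pixel_pitch = 5, min_area_um2 = 1,
                           max_area_um2 = 1e5)
  expect_length(masks, 1)  # diagonal chain is one object
  expect_equal(masks[[1]]$area_px, 3)

  ring <- matrix(0, 20, 20)
  ring[8:12, 8:12] <- 100; ring[10, 10] <- 0
  masks_ring <- segment_primary(ring, tm, pixel_pitch = 5,
                                min_area_um2 = 1, max_area_um2 = 1e6)
  expect_equal(masks_ring[[1]]$area_px, 25)  # hole filled
})

test_that("area gate and threshold monotonicity behave as properties", {
  pitch <- 0.65
  plane <- hard_disk_plane(100, 50, 50, 2, 5000) +   # ~5 um^2 speck
    hard_disk_plane(100, 20, 20, 8, 5000)
  tm <- estimate_threshold(plane, k = 6)
  masks <- segment_primary(plane, tm, pitch, min_area_um2 = 20)
  expect_length(masks, 1)  # speck removed by the lower area gate

  # increasing k never increases the object count
  noisy <- shared_slide()$tiles[[1]]$planes$ck
  n_objects <- vapply(c(2, 4, 6, 9), function(k) {
    length(segment_primary(noisy, estimate_threshold(noisy, k = k), 0.65))
  }, numeric(1))
  expect_true(all(diff(n_objects) <= 0))
})

test_that("segmentation is translation-equivariant", {
  pitch <- 0.65
  base <- hard_disk_plane(100, 40, 40, 8, 5000)
  shifted <- hard_disk_plane(100, 47, 35, 8, 5000)  # +7 in x, -5 in y
  m1 <- segment_primary(base, estimate_threshold(base, k = 6), pitch)
  m2 <- segment_primary(shifted, estimate_threshold(shifted, k = 6), pitch)
  expect_equal(m2[[1]]$centroid_px - m1[[1]]$centroid_px, c(7, -5))
  expect_equal(m2[[1]]$area_px, m1[[1]]$area_px)
})

test_that("nuclear overlap fraction counts supra-threshold mask pixels", {
  pitch <- 1
  ck <- hard_disk_plane(100, 50, 50, 10, 5000)
  mask <- segment_primary(ck, estimate_threshold(ck, k = 6), pitch,
                          max_area_um2 = 1e5)[[1]]
  blank_model <- estimate_threshold(matrix(0, 100, 100))
  expect_equal(nuclear_overlap(mask, matrix(0, 100, 100), blank_model), 0)

  full <- matrix(1000, 100, 100)
  expect_equal(nuclear_overlap(mask, full, blank_model), 1)

  # nuclear stain over the left half of the mask only
  half <- matrix(0, 100, 100)
  half[, 1:51] <- 1000
  frac <- nuclear_overlap(mask, half, blank_model)
  expect_lt(abs(frac - 0.5), 1 / mask$area_px + 0.05)
})

test_that("cd45 correlation has the declared conventions and invariances", {
  pitch <- 1
  set.seed(42)
  ck <- hard_disk_plane(60, 30, 30, 8, 3000) +
    matrix(runif(3600, 0, 10), 60)
  mask <- segment_primary(ck, estimate_threshold(ck, k = 6), pitch,
                          max_area_um2 = 1e5)[[1]]
  expect_equal(cd45_correlation(mask, ck, 2 * ck + 7), 1)
  expect_equal(cd45_correlation(mask, ck, -ck + 50000), -1)
  expect_equal(cd45_correlation(mask, ck, matrix(500, 60, 60)), 0)

  # invariant under positive affine rescaling of either channel
  cd45 <- matrix(runif(3600, 0, 4000), 60)
  r0 <- cd45_correlation(mask, ck, cd45)
  expect_gte(r0, -1); expect_lte(r0, 1)
  expect_equal(cd45_correlation(mask, 3 * ck + 11, cd45), r0)
  expect_equal(cd45_correlation(mask, ck, 0.25 * cd45 + 999), r0)
})

test_that("features of simulated lone cells look like their phenotype", {
  sl <- shared_slide()
  scan <- shared_scan()
  det <- scan$detections
  truth <- sl$truth
  mctc <- dplyr::filter(truth, population == "MCTC")
  # every tumor cell matches exactly one detection with tumor-like features
  for (i in seq_len(nrow(mctc))) {
    d <- sqrt((det$slide_x_um - mctc$x_um[i])^2 +
              (det$slide_y_um - mctc$y_um[i])^2)
    hit <- det[which.min(d), ]
    expect_lt(min(d), 2)
    expect_true(hit$ck_pos)
    expect_lt(hit$cd45_correlation, 0.3)
    expect_gt(hit$nuclear_overlap, 0.2)
  }
  # features are finite and within declared bounds
  expect_true(all(is.finite(det$cd45_correlation)))
  expect_true(all(det$cd45_correlation >= -1 & det$cd45_correlation <= 1))
  expect_true(all(det$nuclear_overlap >= 0 & det$nuclear_overlap <= 1))
  expect_true(all(det$area_um2 > 0))
})

test_that("channel registration recovers injected chromatic shifts", {
  # zero shift recovered within 0.25 px
  clean <- simulate_beads(noise_sd = 10, seed = 8)
  sh0 <- register_channels(clean)
  expect_lt(max(abs(c(sh0$dx, sh0$dy))), 0.25)

  # injected shift (3, -2) recovered within 0.5 px
  tile <- simulate_beads(shifts = list(ck = c(3, -2)), noise_sd = 10,
                         seed = 8)
  sh <- register_channels(tile)
  ck <- sh[sh$channel == "ck", ]
  expect_lt(abs(ck$dx - 3), 0.5)
  expect_lt(abs(ck$dy + 2), 0.5)

  # compensating with the negated estimate leaves < 0.5 px residual
  comp <- apply_chromatic_shift(tile, list(ck = c(-ck$dx, -ck$dy)))
  resid <- register_channels(comp)
  expect_lt(max(abs(c(resid$dx, resid$dy))), 0.5)

  flat <- tile_image(0, 0, lapply(setNames(nm = c("nuclear", "ck", "cd45",
                                                  "marker")),
                                  function(ch) matrix(5, 32, 32)), 0.65)
  expect_error(register_channels(flat),
               class = "ctcscan_calibration_error")
})
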