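test_that("truth counts match the configured population sizes", {
  cfg <- small_cfg(counts = list(wbc = 40, mctc = 3, squamous = 2,
                                 debris = 1), seed = 3)
  sl <- generate_slide(cfg)
  counts <- table(sl$truth$population)
  expect_equal(unname(counts[["WBC"]]), 40)
  expect_equal(unname(counts[["MCTC"]]), 3)
  expect_equal(unname(counts[["SQUAMOUS"]]), 2)
  expect_equal(unname(counts[["DEBRIS"]]), 1)
  expect_equal(sl$truth$cell_id, seq_len(46))

  # empty configuration: only background and noise
  empty <- generate_slide(small_cfg(seed = 1))
  expect_equal(nrow(empty$truth), 0)
  expect_length(empty$tiles, 4)
  for (tl in empty$tiles) {
    expect_lt(max(tl$planes$ck),
              400 + 8 * empty$config$noise_sd)  # background + noise only
  }
})

test_that("identical config and seed give bit-identical slides", {
  cfg <- small_cfg(counts = list(wbc = 30, mctc = 2, squamous = 1,
                                 debris = 1), seed = 9)
  a <- generate_slide(cfg)
  b <- generate_slide(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$tiles, b$tiles)
  c <- generate_slide(small_cfg(counts = list(wbc = 30, mctc = 2,
                                              squamous = 1, debris = 1),
                                seed = 10))
  expect_false(identical(a$tiles, c$tiles))
})

test_that("invalid geometry is rejected", {
  expect_error(sim_config(tile_px = 60, overlap_um = 50),
               class = "ctcscan_config_error")
  expect_error(slide_layout(1, 1, 10, pixel_pitch = 0.65, overlap_um = 50),
               class = "ctcscan_config_error")
})

test_that("rendered cell peak equals background plus amplitude", {
  cfg <- quiet_cfg()
  tile <- generate_slide(cfg)$tiles[[1]]
  # centre on an exact pixel centre: pixel (100, 120)
  rec <- truth_rec("MCTC", x_um = 100 * 0.65, y_um = 120 * 0.65,
                   amp_nuclear = 5000, amp_ck = 4000, amp_marker = 1000)
  out <- render_cell(tile, rec, cfg)
  expect_equal(out$planes$nuclear[121, 101], 300 + 5000)
  expect_equal(out$planes$ck[121, 101], 300 + 4000)
  # zero amplitudes leave the canvas untouched
  zero <- truth_rec("MCTC", 65, 65)
  expect_identical(render_cell(tile, zero, cfg)$planes, tile$planes)
})

test_that("integrated cytokeratin signal matches the closed-form integral", {
  cfg <- quiet_cfg(background_level = 0)
  tile <- generate_slide(cfg)$tiles[[1]]
  rec <- truth_rec("MCTC", x_um = 117, y_um = 117, r_c = 6, amp_ck = 8000)
  out <- render_cell(tile, rec, cfg)
  measured <- sum(out$planes$ck) * cfg$pixel_pitch^2
  # truncated Gaussian disk: integral = 2 pi sigma^2 A (1 - exp(-T^2/2)),
  # sigma = r/2 um, truncation T = 2.5 sigma
  sigma <- 6 / 2
  expected <- 2 * pi * sigma^2 * 8000 * (1 - exp(-2.5^2 / 2))
  expect_lt(abs(measured - expected) / expected, 0.01)
})

test_that("populations do not bleed into their negative channels", {
  cfg <- quiet_cfg()
  tile <- generate_slide(cfg)$tiles[[1]]
  wbc <- render_cell(tile, truth_rec("WBC", 100, 100, r_n = 4.5, r_c = 5,
                                     amp_nuclear = 9000, amp_cd45 = 7000),
                     cfg)
  expect_identical(wbc$planes$ck, tile$planes$ck)
  expect_identical(wbc$planes$marker, tile$planes$marker)
  mctc <- render_cell(tile, truth_rec("MCTC", 100, 100, amp_nuclear = 9000,
                                      amp_ck = 7000, amp_marker = 2000),
                      cfg)
  expect_identical(mctc$planes$cd45, tile$planes$cd45)
})

test_that("a cell in the overlap strip is rendered in both tiles", {
  cfg <- sim_config(grid_rows = 1, grid_cols = 2, tile_px = 360,
                    noise_sd = 0, background_gradient = 0,
                    counts = list(wbc = 0, mctc = 0, squamous = 0,
                                  debris = 0))
  sl <- generate_slide(cfg)
  x_mid <- sl$layout$stride_um + cfg$overlap_um / 2
  rec <- truth_rec("MCTC", x_um = x_mid, y_um = 117, amp_nuclear = 9000,
                   amp_ck = 7000, amp_marker = 1000)
  left <- render_cell(sl$tiles[[1]], rec, cfg)
  right <- render_cell(sl$tiles[[2]], rec, cfg)
  # peak slightly under the amplitude when the centre is off pixel centres
  expect_gt(max(left$planes$ck - sl$tiles[[1]]$planes$ck), 6800)
  expect_gt(max(right$planes$ck - sl$tiles[[2]]$planes$ck), 6800)
})

test_that("rare cells respect the minimum separation rule", {
  cfg <- small_cfg(counts = list(wbc = 100, mctc = 4, squamous = 1,
                                 debris = 0), seed = 21)
  truth <- generate_slide(cfg)$truth
  rare <- dplyr::filter(truth, population != "WBC")
  wbc <- dplyr::filter(truth, population == "WBC")
  for (i in seq_len(nrow(rare))) {
    d_wbc <- sqrt((wbc$x_um - rare$x_um[i])^2 + (wbc$y_um - rare$y_um[i])^2)
    expect_gte(min(d_wbc), cfg$min_separation_um)
    d_rare <- sqrt((rare$x_um[-i] - rare$x_um[i])^2 +
                   (rare$y_um[-i] - rare$y_um[i])^2)
    expect_gte(min(d_rare), cfg$min_separation_um)
  }
})

test_that("declared tumor clusters stay together and count as mctc", {
  cfg <- small_cfg(counts = list(wbc = 0, mctc = 5, squamous = 0,
                                 debris = 0),
                   cluster_spec = list(n_clusters = 1,
                                       cells_per_cluster = 3,
                                       spread_um = 8),
                   seed = 4)
  truth <- generate_slide(cfg)$truth
  expect_equal(sum(truth$population == "MCTC"), 5)
  members <- dplyr::filter(truth, !is.na(cluster_id))
  expect_equal(nrow(members), 3)
  spread <- max(dist(cbind(members$x_um, members$y_um)))
  expect_lte(spread, 2 * 8)
  expect_error(
    small_cfg(counts = list(wbc = 0, mctc = 2, squamous = 0, debris = 0),
              cluster_spec = list(n_clusters = 1, cells_per_cluster = 3)),
    class = "ctcscan_config_error")
})

test_that("chromatic shift is identity at zero and inverts cleanly", {
  tile <- simulate_beads(noise_sd = 0, seed = 2)
  expect_identical(apply_chromatic_shift(tile, list(ck = c(0, 0))), tile)

  fwd <- apply_chromatic_shift(tile, list(ck = c(2, 0)))
  back <- apply_chromatic_shift(fwd, list(ck = c(-2, 0)))
  interior <- 5:250
  expect_lt(max(abs(back$planes$ck[interior, interior] -
                    tile$planes$ck[interior, interior])), 1e-6)

  # integer translations compose additively on the interior
  two_step <- apply_chromatic_shift(
    apply_chromatic_shift(tile, list(ck = c(1, 2))), list(ck = c(2, 1)))
  one_step <- apply_chromatic_shift(tile, list(ck = c(3, 3)))
  expect_lt(max(abs(two_step$planes$ck[interior, interior] -
                    one_step$planes$ck[interior, interior])), 1e-6)

  expect_error(apply_chromatic_shift(tile, list(ck = c(500, 0))),
               class = "ctcscan_config_error")
})

test_that("fractional chromatic shift moves the intensity centroid", {
  tile <- simulate_beads(n_beads = 1, tile_px = 64, noise_sd = 0,
                         background = 0, seed = 3)
  shifted <- apply_chromatic_shift(tile, list(ck = c(1.5, -0.5)))
  cm <- function(p) {
    p <- p - min(p)
    c(sum(col(p) * p), sum(row(p) * p)) / sum(p)
  }
  delta <- cm(shifted$planes$ck) - cm(tile$planes$ck)
  expect_equal(delta[1], 1.5, tolerance = 0.02)
  expect_equal(delta[2], -0.5, tolerance = 0.05)
})
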