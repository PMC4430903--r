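# Shared fixtures: small slide configurations so most tests run on sub-second
# simulations; expensive shared slides are memoized per test run.

# 2x2 grid of 360 px tiles (~0.42 x 0.42 mm slide)
small_cfg <- function(counts = list(wbc = 0, mctc = 0, squamous = 0,
                                    debris = 0),
                      ...) {
  sim_config(grid_rows = 2, grid_cols = 2, tile_px = 360,
             counts = counts, ...)
}

# noise- and gradient-free single tile, flat background
quiet_cfg <- function(counts = list(wbc = 0, mctc = 0, squamous = 0,
                                    debris = 0),
                      background_level = 300, ...) {
  sim_config(grid_rows = 1, grid_cols = 1, tile_px = 360,
             noise_sd = 0, background_gradient = 0,
             background_level = background_level, counts = counts, ...)
}

# one truth record for direct render_cell tests
truth_rec <- function(population, x_um, y_um, r_n = 5, r_c = 6,
                      amp_nuclear = 0, amp_ck = 0, amp_cd45 = 0,
                      amp_marker = 0, cell_id = 1L) {
  tibble::tibble(cell_id = cell_id, population = population,
                 x_um = x_um, y_um = y_um,
                 nuclear_radius_um = r_n, cytoplasm_radius_um = r_c,
                 cluster_id = NA_integer_,
                 amp_nuclear = amp_nuclear, amp_ck = amp_ck,
                 amp_cd45 = amp_cd45, amp_marker = amp_marker)
}

# hard indicator disk used as an independent construction for segmentation
# tests (deliberately not the package's Gaussian renderer)
hard_disk_plane <- function(n, cx, cy, radius_px, amp, background = 0) {
  d2 <- outer((seq_len(n) - 1 - cy)^2, (seq_len(n) - 1 - cx)^2, `+`)
  background + amp * (d2 <= radius_px^2)
}

# minimal detection rows for geometry tests
make_det <- function(object_id, tile_row, tile_col, px_x, px_y, layout,
                     label = "CELL", candidate = TRUE) {
  coords <- tile_to_slide(tile_row, tile_col, px_x, px_y, layout)
  tibble::tibble(object_id = object_id, tile_row = tile_row,
                 tile_col = tile_col, centroid_px_x = px_x,
                 centroid_px_y = px_y, slide_x_um = coords$x_um,
                 slide_y_um = coords$y_um, label = label,
                 candidate = candidate)
}

# ten single-digit spike-in experiments: spiked counts 1,1,1,2,2,3,3,3,5,6
# with identified 1,1,0,2,2,3,3,2,4,4
single_digit_experiments <- function() {
  tibble::tibble(
    experiment = LETTERS[1:10],
    n_spiked = c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L, 5L, 6L),
    n_identified = c(1L, 1L, 0L, 2L, 2L, 3L, 3L, 2L, 4L, 4L))
}

# memoized expensive fixtures (built once per test run)
.fixture_env <- new.env(parent = emptyenv())
memo_fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# shared small slide with all rare populations among leukocytes
shared_slide <- function() {
  memo_fixture("shared_slide", function() {
    generate_slide(small_cfg(
      counts = list(wbc = 150, mctc = 3, squamous = 1, debris = 2),
      seed = 11))
  })
}

shared_scan <- function() {
  memo_fixture("shared_scan", function() {
    sl <- shared_slide()
    scan_slide(sl$tiles, sl$layout)
  })
}
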