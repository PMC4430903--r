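# Synthetic tiled 4-channel slide simulator. Emulates a buffy-coat monolayer
# spread: abundant CD45+ leukocytes, rare spiked tumor cells (nucleated, CK+,
# surface-marker+), occasional CK+ squamous contaminants from venipuncture,
# and anucleate CK debris. Every rendered cell is recorded in a ground-truth
# manifest so detection and classification can be scored exactly.

#' Simulator configuration
#'
#' Defines the slide geometry, optics-free image model and cell populations of
#' a synthetic slide. Cells are rendered as truncated Gaussian intensity disks
#' (sigma = radius / 2, truncated at 2.5 sigma) on a linear background with
#' additive Gaussian read noise, on a 16-bit intensity scale.
#'
#' Populations:
#' * `mctc` — model tumor cell: nuclear disk, cytoplasmic cytokeratin disk,
#'   surface-marker rim (EpCAM/EGFR-like), CD45-negative.
#' * `wbc` — leukocyte: nuclear disk plus CD45, cytokeratin-negative.
#' * `squamous` — skin contaminant: large cytokeratin area with a
#'   proportionally small nucleus, CD45-negative.
#' * `debris` — anucleate irregular cytokeratin fragment.
#'
#' @param grid_rows,grid_cols Tile grid dimensions.
#' @param tile_px Tile edge length in pixels.
#' @param pixel_pitch Micrometres per pixel.
#' @param overlap_um Tile overlap in micrometres.
#' @param background_level Mean background intensity (counts).
#' @param background_gradient Linear background drift in counts per
#'   millimetre of slide `x + y`.
#' @param noise_sd Additive Gaussian noise standard deviation (counts);
#'   clipped at zero.
#' @param counts Named list of population sizes
#'   (`wbc`, `mctc`, `squamous`, `debris`).
#' @param amplitudes Per-population, per-channel `c(min, max)` peak-intensity
#'   ranges (counts); amplitudes are drawn uniformly.
#' @param geometry Per-population `c(nuclear_radius_um, cytoplasm_radius_um)`.
#' @param chromatic_shift Named list of `(dx, dy)` pixel shifts applied to
#'   non-reference channels (the nuclear channel is the reference). The
#'   default is no shift, i.e. channels already co-registered, as after
#'   instrument-side aberration compensation.
#' @param min_separation_um Minimum centre-to-centre clearance enforced when
#'   placing rare cells (see Details).
#' @param cluster_spec Optional list `(n_clusters, cells_per_cluster,
#'   spread_um)` declaring tumor-cell clusters; cluster members are exempt
#'   from the separation rule among themselves and count towards
#'   `counts$mctc`.
#' @param seed Integer seed; identical configuration + seed gives
#'   bit-identical slides.
#'
#' @details
#' Leukocytes are placed uniformly over the slide with overlaps allowed.
#' Rare cells (tumor, squamous, debris, cluster centres) are
#' rejection-resampled until their centre distance to every previously placed
#' cell is at least `max(min_separation_um, r_a + r_b + 5)` micrometres,
#' where `r` is a cell's rendered extent; this keeps rare cells from being
#' swallowed by leukocyte staining or coalescing with each other. Rare-cell
#' centres are inset from the slide edge by their rendered extent so cells
#' are imaged whole.
#'
#' @return A `sim_config` object.
#' @export
sim_config <- function(grid_rows = 3, grid_cols = 3, tile_px = 900,
                       pixel_pitch = 0.65, overlap_um = 50,
                       background_level = 300, background_gradient = 20,
                       noise_sd = 50,
                       counts = list(),
                       amplitudes = list(),
                       geometry = list(),
                       chromatic_shift = list(),
                       min_separation_um = 30,
                       cluster_spec = NULL,
                       seed = 1L) {
  counts <- utils::modifyList(
    list(wbc = 2000, mctc = 3, squamous = 2, debris = 0), counts)
  amplitudes <- utils::modifyList(list(
    mctc     = list(nuclear = c(12000, 20000), ck = c(8000, 15000),
                    cd45 = c(0, 0), marker = c(3000, 8000)),
    wbc      = list(nuclear = c(10000, 18000), ck = c(0, 0),
                    cd45 = c(5000, 12000), marker = c(0, 0)),
    squamous = list(nuclear = c(8000, 14000), ck = c(6000, 12000),
                    cd45 = c(0, 0), marker = c(0, 0)),
    debris   = list(nuclear = c(0, 0), ck = c(2000, 6000),
                    cd45 = c(0, 0), marker = c(0, 0))
  ), amplitudes)
  geometry <- utils::modifyList(list(
    mctc     = c(nuclear_radius_um = 5,  cytoplasm_radius_um = 6),
    wbc      = c(nuclear_radius_um = 4.5, cytoplasm_radius_um = 5),
    squamous = c(nuclear_radius_um = 10, cytoplasm_radius_um = 18),
    debris   = c(nuclear_radius_um = 0,  cytoplasm_radius_um = 2)
  ), geometry)
  chromatic_shift <- utils::modifyList(
    list(ck = c(0, 0), cd45 = c(0, 0), marker = c(0, 0)), chromatic_shift)

  stopifnot(all(unlist(counts) >= 0), all(unlist(amplitudes) >= 0),
            noise_sd >= 0, background_level >= 0, min_separation_um >= 0)
  if (!is.null(cluster_spec)) {
    cluster_spec <- utils::modifyList(
      list(n_clusters = 1, cells_per_cluster = 3, spread_um = 10),
      cluster_spec)
    if (cluster_spec$n_clusters * cluster_spec$cells_per_cluster >
        counts$mctc) {
      abort("cluster_spec requires more mctc cells than counts$mctc",
            class = "ctcscan_config_error")
    }
  }
  layout <- slide_layout(grid_rows, grid_cols, tile_px, pixel_pitch,
                         overlap_um)  # validates the geometry
  structure(list(
    grid_rows = layout$grid_rows, grid_cols = layout$grid_cols,
    tile_px = layout$tile_px, pixel_pitch = pixel_pitch,
    overlap_um = overlap_um, channels = CHANNELS,
    background_level = background_level,
    background_gradient = background_gradient, noise_sd = noise_sd,
    counts = counts, amplitudes = amplitudes, geometry = geometry,
    chromatic_shift = chromatic_shift,
    min_separation_um = min_separation_um, cluster_spec = cluster_spec,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %dx%d tiles of %d px, seed %d\n",
              x$grid_rows, x$grid_cols, x$tile_px, x$seed))
  cat("  counts:", paste(names(x$counts), unlist(x$counts), sep = "=",
                         collapse = " "), "\n")
  invisible(x)
}

sim_layout <- function(cfg) {
  slide_layout(cfg$grid_rows, cfg$grid_cols, cfg$tile_px, cfg$pixel_pitch,
               cfg$overlap_um, cfg$channels)
}

#' A single field-of-view image
#'
#' @param row,col 0-based tile grid indices.
#' @param planes Named list of equally sized intensity matrices
#'   (rows = image y, columns = image x), one per channel.
#' @param pixel_pitch Micrometres per pixel.
#'
#' @return A `tile_image` object.
#' @export
tile_image <- function(row, col, planes, pixel_pitch) {
  dims <- unique(lapply(planes, dim))
  if (length(dims) != 1) {
    abort("all planes of a tile must have identical dimensions",
          class = "ctcscan_format_error")
  }
  structure(list(row = as.integer(row), col = as.integer(col),
                 planes = planes, pixel_pitch = pixel_pitch),
            class = "tile_image")
}

#' @export
print.tile_image <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf("<tile_image> (%d,%d) %dx%d px, channels: %s\n",
              x$row, x$col, d[1], d[2],
              paste(names(x$planes), collapse = ", ")))
  invisible(x)
}

# rendered extent (um) of each population = farthest radius at which any
# channel profile is non-zero
render_extent_um <- function(population, geom) {
  r_n <- geom[["nuclear_radius_um"]]
  r_c <- geom[["cytoplasm_radius_um"]]
  switch(population,
    MCTC     = max(1.25 * r_n, 1.25 * r_c, 1.625 * r_c),  # marker rim
    WBC      = max(1.25 * r_n, 1.25 * r_c),
    SQUAMOUS = max(1.25 * r_n, 1.25 * r_c),
    DEBRIS   = 1.25 * r_c + 3.6,                           # offset fragments
    abort(paste("unknown population", population)))
}

draw_amplitudes <- function(pop_key, n, cfg) {
  amps <- cfg$amplitudes[[pop_key]]
  out <- lapply(CHANNELS, function(ch) {
    rg <- amps[[ch]]
    if (rg[1] == rg[2]) rep(rg[1], n) else runif(n, rg[1], rg[2])
  })
  names(out) <- paste0("amp_", CHANNELS)
  tibble::as_tibble(out)
}

place_rare <- function(n, extent_um, others, layout, cfg, max_tries = 20000) {
  # others: tibble with x_um, y_um, r_um of already-placed cells
  xs <- ys <- numeric(n)
  lo_x <- extent_um; hi_x <- layout$width_um - extent_um
  lo_y <- extent_um; hi_y <- layout$height_um - extent_um
  if (hi_x <= lo_x || hi_y <= lo_y) {
    abort("slide too small for the requested cell size",
          class = "ctcscan_config_error")
  }
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      x <- runif(1, lo_x, hi_x); y <- runif(1, lo_y, hi_y)
      if (nrow(others) > 0) {
        need <- pmax(cfg$min_separation_um, extent_um + others$r_um + 5)
        d2 <- (others$x_um - x)^2 + (others$y_um - y)^2
        if (any(d2 < need^2)) next
      }
      xs[i] <- x; ys[i] <- y
      others <- dplyr::bind_rows(
        others, tibble::tibble(x_um = x, y_um = y, r_um = extent_um))
      placed <- TRUE
      break
    }
    if (!placed) {
      abort("could not place a rare cell with the required separation; the slide is too crowded",
            class = "ctcscan_config_error")
    }
  }
  list(x = xs, y = ys, others = others)
}

#' Generate a synthetic tiled slide with ground truth
#'
#' Places all configured cells on the slide, renders every tile of the grid
#' (each cell appears in every tile whose field of view contains it, so cells
#' in overlap strips are imaged in multiple tiles), applies any configured
#' chromatic shift, and adds background and noise. The returned truth
#' manifest records every cell's population, slide position, geometry and
#' per-channel peak amplitudes.
#'
#' @param cfg A [sim_config()].
#'
#' @return A list with elements `tiles` (list of [tile_image()]), `truth`
#'   (tibble, one row per cell), `layout` ([slide_layout()]) and `config`.
#' @export
generate_slide <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  layout <- sim_layout(cfg)
  withr::local_seed(cfg$seed)

  truth <- list()
  placed <- tibble::tibble(x_um = double(0), y_um = double(0),
                           r_um = double(0))

  # leukocytes first: uniform, overlaps allowed
  n_wbc <- cfg$counts$wbc
  if (n_wbc > 0) {
    g <- cfg$geometry$wbc
    x <- runif(n_wbc, 0, layout$width_um)
    y <- runif(n_wbc, 0, layout$height_um)
    truth$wbc <- dplyr::bind_cols(
      tibble::tibble(population = "WBC", x_um = x, y_um = y,
                     nuclear_radius_um = g[["nuclear_radius_um"]],
                     cytoplasm_radius_um = g[["cytoplasm_radius_um"]],
                     cluster_id = NA_integer_),
      draw_amplitudes("wbc", n_wbc, cfg))
    placed <- tibble::tibble(
      x_um = x, y_um = y, r_um = render_extent_um("WBC", cfg$geometry$wbc))
  }

  # tumor cells: clustered members first (exempt from separation among
  # themselves), then singletons
  n_mctc <- cfg$counts$mctc
  if (n_mctc > 0) {
    g <- cfg$geometry$mctc
    ext <- render_extent_um("MCTC", g)
    xs <- ys <- numeric(0); cl <- integer(0)
    if (!is.null(cfg$cluster_spec)) {
      cs <- cfg$cluster_spec
      centre_ext <- ext + cs$spread_um
      ctr <- place_rare(cs$n_clusters, centre_ext, placed, layout, cfg)
      placed <- ctr$others
      for (k in seq_len(cs$n_clusters)) {
        ang <- runif(cs$cells_per_cluster, 0, 2 * pi)
        rad <- runif(cs$cells_per_cluster, 0, cs$spread_um)
        xs <- c(xs, ctr$x[k] + rad * cos(ang))
        ys <- c(ys, ctr$y[k] + rad * sin(ang))
        cl <- c(cl, rep(k, cs$cells_per_cluster))
      }
    }
    n_single <- n_mctc - length(xs)
    if (n_single > 0) {
      sg <- place_rare(n_single, ext, placed, layout, cfg)
      placed <- sg$others
      xs <- c(xs, sg$x); ys <- c(ys, sg$y)
      cl <- c(cl, rep(NA_integer_, n_single))
    }
    truth$mctc <- dplyr::bind_cols(
      tibble::tibble(population = "MCTC", x_um = xs, y_um = ys,
                     nuclear_radius_um = g[["nuclear_radius_um"]],
                     cytoplasm_radius_um = g[["cytoplasm_radius_um"]],
                     cluster_id = cl),
      draw_amplitudes("mctc", n_mctc, cfg))
  }

  for (pop in c("squamous", "debris")) {
    n <- cfg$counts[[pop]]
    if (n == 0) next
    g <- cfg$geometry[[pop]]
    pop_lab <- toupper(pop)
    ext <- render_extent_um(pop_lab, g)
    pl <- place_rare(n, ext, placed, layout, cfg)
    placed <- pl$others
    truth[[pop]] <- dplyr::bind_cols(
      tibble::tibble(population = pop_lab, x_um = pl$x, y_um = pl$y,
                     nuclear_radius_um = g[["nuclear_radius_um"]],
                     cytoplasm_radius_um = g[["cytoplasm_radius_um"]],
                     cluster_id = NA_integer_),
      draw_amplitudes(pop, n, cfg))
  }

  truth <- dplyr::bind_rows(truth)
  if (nrow(truth) == 0) {
    truth <- tibble::tibble(
      population = character(0), x_um = double(0), y_um = double(0),
      nuclear_radius_um = double(0), cytoplasm_radius_um = double(0),
      cluster_id = integer(0), amp_nuclear = double(0), amp_ck = double(0),
      amp_cd45 = double(0), amp_marker = double(0))
  }
  truth <- dplyr::mutate(truth, cell_id = dplyr::row_number(),
                         .before = 1)

  # render every tile; noise is drawn per tile in row-major order so the
  # whole slide is a deterministic function of config + seed
  truth_rows <- lapply(seq_len(nrow(truth)),
                       function(i) lapply(truth, `[[`, i))
  ext <- vapply(truth_rows, function(rec) {
    render_extent_um(rec$population,
                     c(nuclear_radius_um = rec$nuclear_radius_um,
                       cytoplasm_radius_um = rec$cytoplasm_radius_um))
  }, numeric(1))
  tiles <- vector("list", layout$grid_rows * layout$grid_cols)
  idx <- 1
  for (r in seq_len(layout$grid_rows) - 1L) {
    for (cc in seq_len(layout$grid_cols) - 1L) {
      tiles[[idx]] <- render_tile(r, cc, truth_rows, ext, cfg, layout)
      idx <- idx + 1
    }
  }
  list(tiles = tiles, truth = truth, layout = layout, config = cfg)
}

blank_tile <- function(row, col, cfg, layout) {
  np <- layout$tile_px
  ox <- col * layout$stride_um
  oy <- row * layout$stride_um
  # linear background drift along x + y, in counts per mm
  px_um <- ox + (seq_len(np) - 1) * layout$pixel_pitch
  py_um <- oy + (seq_len(np) - 1) * layout$pixel_pitch
  bg <- cfg$background_level +
    cfg$background_gradient * (outer(py_um, px_um, `+`) / 2000)
  planes <- lapply(CHANNELS, function(ch) bg)
  names(planes) <- CHANNELS
  tile_image(row, col, planes, layout$pixel_pitch)
}

render_tile <- function(row, col, truth_rows, ext, cfg, layout) {
  tile <- blank_tile(row, col, cfg, layout)
  ox <- col * layout$stride_um
  oy <- row * layout$stride_um
  ext_tile <- layout$tile_px * layout$pixel_pitch
  if (length(truth_rows) > 0) {
    x <- vapply(truth_rows, `[[`, numeric(1), "x_um")
    y <- vapply(truth_rows, `[[`, numeric(1), "y_um")
    in_view <- x + ext >= ox & x - ext < ox + ext_tile &
               y + ext >= oy & y - ext < oy + ext_tile
    dims <- c(layout$tile_px, layout$tile_px)
    acc <- lapply(setNames(CHANNELS, CHANNELS),
                  function(ch) list(idx = list(), val = list()))
    for (i in which(in_view)) {
      rec <- truth_rows[[i]]
      rec$.tile_row <- row; rec$.tile_col <- col
      for (ch in names(cb <- cell_contribs(rec, layout, dims))) {
        acc[[ch]]$idx <- c(acc[[ch]]$idx, list(cb[[ch]]$idx))
        acc[[ch]]$val <- c(acc[[ch]]$val, list(cb[[ch]]$val))
      }
    }
    # one aggregated in-place update per channel (overlapping cells sum)
    for (ch in CHANNELS) {
      if (length(acc[[ch]]$idx) == 0) next
      idx <- unlist(acc[[ch]]$idx, use.names = FALSE)
      val <- unlist(acc[[ch]]$val, use.names = FALSE)
      s <- rowsum(val, idx)
      ii <- as.integer(rownames(s))
      p <- tile$planes[[ch]]
      p[ii] <- p[ii] + s[, 1]
      tile$planes[[ch]] <- p
    }
  }
  if (any(vapply(cfg$chromatic_shift, function(s) any(s != 0), logical(1)))) {
    tile <- apply_chromatic_shift(tile, cfg$chromatic_shift)
  }
  if (cfg$noise_sd > 0) {
    for (ch in CHANNELS) {
      n <- length(tile$planes[[ch]])
      tile$planes[[ch]] <- tile$planes[[ch]] +
        matrix(rnorm(n, 0, cfg$noise_sd), nrow = layout$tile_px)
    }
  }
  for (ch in CHANNELS) {
    tile$planes[[ch]] <- round(pmin(pmax(tile$planes[[ch]], 0),
                                    MAX_INTENSITY))
  }
  tile
}

# window of a radial profile: linear indices into the plane plus the values
# to add there, or NULL when the window misses the plane
profile_contrib <- function(dims, cx_px, cy_px, rmax, value_fn) {
  nr <- dims[1]; nc <- dims[2]
  i0 <- max(1, floor(cy_px + 1 - rmax)); i1 <- min(nr, ceiling(cy_px + 1 + rmax))
  j0 <- max(1, floor(cx_px + 1 - rmax)); j1 <- min(nc, ceiling(cx_px + 1 + rmax))
  if (i0 > i1 || j0 > j1) return(NULL)
  d2 <- outer(((i0:i1) - 1 - cy_px)^2, ((j0:j1) - 1 - cx_px)^2, `+`)
  val <- value_fn(d2)
  keep <- val > 0
  if (!any(keep)) return(NULL)
  idx <- outer(i0:i1, (j0:j1 - 1) * nr, `+`)
  list(idx = idx[keep], val = val[keep])
}

# truncated Gaussian disk: peak `amp` at the centre, sigma = radius / 2,
# zero beyond 2.5 sigma
disk_contrib <- function(dims, cx_px, cy_px, radius_um, amp, pitch) {
  if (amp <= 0 || radius_um <= 0) return(NULL)
  sigma <- radius_um / 2 / pitch
  rmax <- 2.5 * sigma
  profile_contrib(dims, cx_px, cy_px, rmax, function(d2) {
    v <- amp * exp(-d2 / (2 * sigma^2))
    v[d2 > rmax^2] <- 0
    v
  })
}

# membrane-like ring: peak `amp` on the circle d = radius, Gaussian fall-off
# with sigma_r = radius / 4, zero beyond radius + 2.5 sigma_r
rim_contrib <- function(dims, cx_px, cy_px, radius_um, amp, pitch) {
  if (amp <= 0 || radius_um <= 0) return(NULL)
  r0 <- radius_um / pitch
  sigma <- r0 / 4
  rmax <- r0 + 2.5 * sigma
  profile_contrib(dims, cx_px, cy_px, rmax, function(d2) {
    d <- sqrt(d2)
    v <- amp * exp(-(d - r0)^2 / (2 * sigma^2))
    v[d > rmax] <- 0
    v
  })
}

apply_contrib <- function(plane, contrib) {
  if (is.null(contrib)) return(plane)
  plane[contrib$idx] <- plane[contrib$idx] + contrib$val
  plane
}

add_disk <- function(plane, cx_px, cy_px, radius_um, amp, pitch) {
  apply_contrib(plane, disk_contrib(dim(plane), cx_px, cy_px, radius_um,
                                    amp, pitch))
}

add_rim <- function(plane, cx_px, cy_px, radius_um, amp, pitch) {
  apply_contrib(plane, rim_contrib(dim(plane), cx_px, cy_px, radius_um,
                                   amp, pitch))
}

# per-channel (index, value) contributions of one cell to a tile
cell_contribs <- function(rec, layout, dims) {
  pitch <- layout$pixel_pitch
  cx <- (rec$x_um - rec$.tile_col * layout$stride_um) / pitch
  cy <- (rec$y_um - rec$.tile_row * layout$stride_um) / pitch
  r_n <- rec$nuclear_radius_um
  r_c <- rec$cytoplasm_radius_um
  out <- list()
  if (rec$population == "MCTC") {
    out$nuclear <- disk_contrib(dims, cx, cy, r_n, rec$amp_nuclear, pitch)
    out$ck      <- disk_contrib(dims, cx, cy, r_c, rec$amp_ck, pitch)
    out$marker  <- rim_contrib(dims, cx, cy, r_c, rec$amp_marker, pitch)
  } else if (rec$population == "WBC") {
    out$nuclear <- disk_contrib(dims, cx, cy, r_n, rec$amp_nuclear, pitch)
    out$cd45    <- disk_contrib(dims, cx, cy, r_c, rec$amp_cd45, pitch)
  } else if (rec$population == "SQUAMOUS") {
    out$nuclear <- disk_contrib(dims, cx, cy, r_n, rec$amp_nuclear, pitch)
    out$ck      <- disk_contrib(dims, cx, cy, r_c, rec$amp_ck, pitch)
  } else if (rec$population == "DEBRIS") {
    # irregular fragment: three small overlapping blobs on a deterministic
    # spiral derived from the cell id (no RNG at render time)
    pieces <- lapply(0:2, function(k) {
      ang <- rec$cell_id * 2.399963 + k * 2.199115
      off <- 1.2 * (k + 1)
      disk_contrib(dims, cx + off * cos(ang) / pitch,
                   cy + off * sin(ang) / pitch, r_c, rec$amp_ck, pitch)
    })
    pieces <- pieces[!vapply(pieces, is.null, logical(1))]
    if (length(pieces) > 0) {
      out$ck <- list(idx = unlist(lapply(pieces, `[[`, "idx")),
                     val = unlist(lapply(pieces, `[[`, "val")))
    }
  } else {
    abort(paste("unknown population", rec$population))
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Render one cell into a tile
#'
#' Adds the cell's noise-free intensity profile to every channel it stains.
#' The profile peak equals the record's per-channel amplitude. Records whose
#' footprint misses the tile's field of view are a no-op.
#'
#' @param canvas A [tile_image()].
#' @param rec One row of a truth manifest.
#' @param cfg The [sim_config()] used to build the slide.
#'
#' @return The tile with the cell rendered.
#' @export
render_cell <- function(canvas, rec, cfg) {
  render_cell_impl(canvas, as.list(rec), sim_layout(cfg))
}

render_cell_impl <- function(canvas, rec, layout) {
  rec$.tile_row <- canvas$row; rec$.tile_col <- canvas$col
  cb <- cell_contribs(rec, layout, dim(canvas$planes[[1]]))
  for (ch in names(cb)) {
    canvas$planes[[ch]] <- apply_contrib(canvas$planes[[ch]], cb[[ch]])
  }
  canvas
}

#' Shift channels to emulate (or compensate) chromatic aberration
#'
#' Translates each named channel by its `(dx, dy)` pixel offset with bilinear
#' interpolation for fractional shifts; uncovered border pixels are zero.
#' Channels without an entry (notably the reference nuclear channel) are
#' untouched.
#'
#' @param tile A [tile_image()].
#' @param shifts Named list of `c(dx, dy)` pixel shifts (x along columns,
#'   y along rows; positive moves content towards larger indices).
#'
#' @return The shifted tile.
#' @export
apply_chromatic_shift <- function(tile, shifts) {
  np <- dim(tile$planes[[1]])
  for (ch in names(shifts)) {
    s <- shifts[[ch]]
    if (all(s == 0)) next
    if (any(abs(s) >= np)) {
      abort(sprintf("chromatic shift for channel '%s' exceeds the tile", ch),
            class = "ctcscan_config_error")
    }
    if (!ch %in% names(tile$planes)) {
      abort(sprintf("unknown channel '%s' in shifts", ch),
            class = "ctcscan_config_error")
    }
    # EBImage::translate shifts dim1 (rows) by v[1] and dim2 (cols) by v[2]
    tile$planes[[ch]] <- as.matrix(EBImage::translate(
      tile$planes[[ch]], v = c(s[2], s[1]), filter = "bilinear", bg.col = 0))
  }
  tile
}

#' Simulate a bead calibration tile
#'
#' Multispectral beads appear with identical structure in all four channels,
#' which is what channel registration needs. An optional chromatic shift can
#' be injected to create a known misregistration.
#'
#' @param n_beads Number of beads.
#' @param tile_px Tile edge in pixels.
#' @param pixel_pitch Micrometres per pixel.
#' @param bead_radius_um Bead radius.
#' @param amplitude Peak bead intensity.
#' @param background,noise_sd Background level and noise sd (counts).
#' @param shifts Optional chromatic shift list as in
#'   [apply_chromatic_shift()].
#' @param seed Integer seed.
#'
#' @return A [tile_image()].
#' @export
simulate_beads <- function(n_beads = 25, tile_px = 256, pixel_pitch = 0.65,
                           bead_radius_um = 2, amplitude = 20000,
                           background = 300, noise_sd = 20,
                           shifts = NULL, seed = 1L) {
  withr::local_seed(seed)
  margin <- 2.5 * bead_radius_um / 2 / pixel_pitch + max(2, abs(unlist(shifts %||% 0)))
  cx <- runif(n_beads, margin, tile_px - 1 - margin)
  cy <- runif(n_beads, margin, tile_px - 1 - margin)
  base <- matrix(background, tile_px, tile_px)
  for (i in seq_len(n_beads)) {
    base <- add_disk(base, cx[i], cy[i], bead_radius_um, amplitude,
                     pixel_pitch)
  }
  planes <- lapply(CHANNELS, function(ch) base)
  names(planes) <- CHANNELS
  tile <- tile_image(0L, 0L, planes, pixel_pitch)
  if (!is.null(shifts)) tile <- apply_chromatic_shift(tile, shifts)
  if (noise_sd > 0) {
    for (ch in CHANNELS) {
      tile$planes[[ch]] <- pmax(
        tile$planes[[ch]] +
          matrix(rnorm(tile_px^2, 0, noise_sd), tile_px), 0)
    }
  }
  tile
}
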