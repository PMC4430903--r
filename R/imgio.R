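# Readers and writers: tilesets as multi-page 16-bit TIFF plus a JSON layout
# manifest, detections as CSV, truth manifests as JSON/CSV, glyphs as
# per-channel TIFF. All pixel I/O is lossless for integer-valued planes on
# the 16-bit scale.

tile_filename <- function(row, col) sprintf("tile_r%03d_c%03d.tif", row, col)

write_plane_tiff <- function(planes, path) {
  tiff::writeTIFF(lapply(planes, function(p) {
    pmin(pmax(p, 0), MAX_INTENSITY) / MAX_INTENSITY
  }), path, bits.per.sample = 16, compression = "none")
}

read_plane_tiff <- function(path) {
  lapply(tiff::readTIFF(path, all = TRUE), function(p) round(p * MAX_INTENSITY))
}

#' Write a tileset to disk
#'
#' Each tile becomes one multi-page TIFF (one 16-bit page per channel, in
#' the channel order recorded in the manifest); the layout and file map go
#' into `layout.json`.
#'
#' @param tiles List of [tile_image()]s.
#' @param layout A [slide_layout()].
#' @param dir Output directory (created if missing).
#'
#' @return `dir`, invisibly.
#' @export
write_tileset <- function(tiles, layout, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tl in tiles) {
    if (!identical(names(tl$planes), layout$channels)) {
      abort("tile channels do not match the layout channel order",
            class = "ctcscan_format_error")
    }
    write_plane_tiff(tl$planes, file.path(dir, tile_filename(tl$row, tl$col)))
  }
  manifest <- list(
    grid_rows = layout$grid_rows, grid_cols = layout$grid_cols,
    tile_px = layout$tile_px, pixel_pitch = layout$pixel_pitch,
    overlap_um = layout$overlap_um, channels = layout$channels,
    tiles = purrr::map(tiles, function(tl) {
      list(row = tl$row, col = tl$col, file = tile_filename(tl$row, tl$col))
    }))
  jsonlite::write_json(manifest, file.path(dir, "layout.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a tileset from disk
#'
#' @param dir Directory written by [write_tileset()].
#'
#' @return A list with `tiles` and `layout`.
#' @export
read_tileset <- function(dir) {
  mpath <- file.path(dir, "layout.json")
  if (!file.exists(mpath)) {
    abort(sprintf("no layout.json manifest in '%s'", dir),
          class = "ctcscan_format_error")
  }
  m <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  layout <- slide_layout(m$grid_rows, m$grid_cols, m$tile_px, m$pixel_pitch,
                         m$overlap_um, m$channels)
  tiles <- purrr::pmap(m$tiles, function(row, col, file) {
    path <- file.path(dir, file)
    if (!file.exists(path)) {
      abort(sprintf("missing tile file for tile (%d,%d): %s", row, col, file),
            class = "ctcscan_format_error")
    }
    planes <- read_plane_tiff(path)
    if (length(planes) != length(layout$channels)) {
      abort(sprintf("tile (%d,%d) has %d pages, expected %d channels",
                    row, col, length(planes), length(layout$channels)),
            class = "ctcscan_format_error")
    }
    names(planes) <- layout$channels
    tile_image(row, col, planes, layout$pixel_pitch)
  })
  list(tiles = tiles, layout = layout)
}

detection_columns <- c(
  "object_id", "tile_row", "tile_col", "centroid_px_x", "centroid_px_y",
  "slide_x_um", "slide_y_um", "area_px", "area_um2", "equiv_diameter_um",
  "mean_nuclear", "max_nuclear", "mean_ck", "max_ck", "mean_cd45",
  "max_cd45", "mean_marker", "max_marker", "nuclear_overlap", "nc_ratio",
  "n_nuclear_components", "cd45_correlation", "nuc_pos", "ck_pos",
  "cd45_pos", "marker_pos", "candidate", "label", "rejected_by")

#' Write / read a detection table
#'
#' Comma-separated, UTF-8, `.` decimal, fixed header; numeric columns round
#' trip at full precision. Reading validates the label column.
#'
#' @param detections Detection tibble.
#' @param path CSV path.
#'
#' @return `write_detections` returns `path` invisibly; `read_detections`
#'   returns the tibble.
#' @export
write_detections <- function(detections, path) {
  missing_cols <- setdiff(detection_columns, names(detections))
  if (length(missing_cols) > 0) {
    abort(paste("detection table is missing columns:",
                paste(missing_cols, collapse = ", ")),
          class = "ctcscan_format_error")
  }
  readr::write_csv(detections[, union(detection_columns,
                                      names(detections))], path)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           label = readr::col_character(),
                           rejected_by = readr::col_character()))
  missing_cols <- setdiff(detection_columns, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste("detection file is missing columns:",
                paste(missing_cols, collapse = ", ")),
          class = "ctcscan_format_error")
  }
  bad <- setdiff(unique(tbl$label), LABELS)
  if (length(bad) > 0) {
    abort(paste("unknown label value(s):", paste(bad, collapse = ", ")),
          class = "ctcscan_format_error")
  }
  bad_r <- setdiff(unique(tbl$rejected_by), REJECT_REASONS)
  if (length(bad_r) > 0) {
    abort(paste("unknown rejected_by value(s):",
                paste(bad_r, collapse = ", ")),
          class = "ctcscan_format_error")
  }
  tbl
}

#' Write a ground-truth manifest
#'
#' JSON carries the full manifest (records plus the generating configuration
#' and seed); CSV carries one row per cell.
#'
#' @param truth Truth tibble from [generate_slide()].
#' @param cfg The generating [sim_config()].
#' @param path Output path; `.json` or `.csv` decides the format.
#'
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, cfg, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(seed = cfg$seed, config = unclass(cfg),
                              records = truth),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_csv(truth, path)
  }
  invisible(path)
}

#' Write a review glyph to disk
#'
#' One 16-bit TIFF per channel (`<id>_<channel>.tif`), plus an optional
#' contrast-stretched 8-bit RGB composite (`<id>_composite.tif`; red =
#' marker, green = cytokeratin, blue = nuclear).
#'
#' @param glyph A [make_glyph()] result.
#' @param dir Output directory (created if missing).
#' @param object_id Identifier encoded in the filenames.
#' @param composite Also write the RGB composite?
#'
#' @return Character vector of the files written, invisibly.
#' @export
write_glyph <- function(glyph, dir, object_id, composite = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (ch in names(glyph$planes)) {
    f <- file.path(dir, sprintf("glyph_%06d_%s.tif", object_id, ch))
    write_plane_tiff(glyph$planes[ch], f)
    files <- c(files, f)
  }
  if (composite) {
    stretch <- function(p) {
      rg <- range(p)
      if (rg[2] > rg[1]) (p - rg[1]) / (rg[2] - rg[1]) else p * 0
    }
    rgb <- array(0, dim = c(dim(glyph$planes[[1]]), 3))
    rgb[, , 1] <- stretch(glyph$planes$marker)
    rgb[, , 2] <- stretch(glyph$planes$ck)
    rgb[, , 3] <- stretch(glyph$planes$nuclear)
    f <- file.path(dir, sprintf("glyph_%06d_composite.tif", object_id))
    tiff::writeTIFF(rgb, f, bits.per.sample = 8, compression = "none")
    files <- c(files, f)
  }
  invisible(files)
}

#' Read and validate a run configuration JSON
#'
#' Configuration schema for command-line runs: top-level keys `sim`
#' (arguments of [sim_config()]), `rules` (arguments of [rule_config()]),
#' `k` (threshold multiplier), `dedup_radius_um`, and `seed`. Unknown keys
#' and malformed values raise a validation error.
#'
#' @param path JSON file.
#'
#' @return A list with validated `sim`, `rules`, `k`, `dedup_radius_um`,
#'   `seed`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("sim", "rules", "k", "dedup_radius_um", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste("unknown config keys:", paste(unknown, collapse = ", ")),
          class = "ctcscan_config_error")
  }
  sim_args <- as.list(raw$sim %||% list())
  allowed_sim <- setdiff(names(formals(sim_config)), "")
  bad <- setdiff(names(sim_args), allowed_sim)
  if (length(bad) > 0) {
    abort(paste("unknown sim config keys:", paste(bad, collapse = ", ")),
          class = "ctcscan_config_error")
  }
  rule_args <- as.list(raw$rules %||% list())
  bad <- setdiff(names(rule_args), names(formals(rule_config)))
  if (length(bad) > 0) {
    abort(paste("unknown rules config keys:", paste(bad, collapse = ", ")),
          class = "ctcscan_config_error")
  }
  list(sim = sim_args, rules = rule_args,
       k = raw$k %||% 6, dedup_radius_um = raw$dedup_radius_um %||% 15,
       seed = raw$seed %||% 1L)
}
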