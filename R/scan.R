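# Whole-slide scan pipeline: (optional) chromatic compensation, per-tile
# adaptive thresholds, cytokeratin-primary segmentation, feature extraction,
# classification, tile-to-slide mapping, cross-tile deduplication and
# picklist generation.

#' Scan one tile
#'
#' Runs the per-tile stages and returns a feature/classification tibble with
#' slide coordinates. The nuclear channel is excluded from detection
#' thresholding (its threshold is computed the same way but used only for
#' the nuclear-overlap and nuclear:cytoplasm measurements).
#'
#' @param tile A [tile_image()].
#' @param layout A [slide_layout()].
#' @param rules A [rule_config()].
#' @param k Threshold multiplier for [estimate_threshold()].
#' @param min_area_um2,max_area_um2 Segmentation area gate.
#' @param shifts Optional chromatic shifts (as estimated by
#'   [register_channels()]) to compensate before analysis.
#'
#' @return A tibble of classified detections for this tile (possibly empty).
#' @export
scan_tile <- function(tile, layout, rules = rule_config(), k = 6,
                      min_area_um2 = 20, max_area_um2 = 2000,
                      shifts = NULL) {
  if (!is.null(shifts)) {
    neg <- lapply(split(shifts, shifts$channel),
                  function(s) c(-s$dx, -s$dy))
    tile <- apply_chromatic_shift(tile, neg)
  }
  models <- lapply(setNames(CHANNELS, CHANNELS), function(ch) {
    estimate_threshold(tile$planes[[ch]], k = k, channel = ch)
  })
  masks <- segment_primary(tile$planes$ck, models$ck, layout$pixel_pitch,
                           min_area_um2, max_area_um2)
  if (length(masks) == 0) return(empty_detections())
  feats <- purrr::map(masks, function(m) extract_features(tile, m, models))
  feats <- dplyr::bind_rows(feats)
  out <- classify_objects(feats, rules, models)
  coords <- tile_to_slide(tile$row, tile$col, out$centroid_px_x,
                          out$centroid_px_y, layout)
  out |>
    dplyr::mutate(tile_row = tile$row, tile_col = tile$col,
                  slide_x_um = coords$x_um, slide_y_um = coords$y_um)
}

empty_detections <- function() {
  tibble::tibble(
    centroid_px_x = double(0), centroid_px_y = double(0),
    area_px = double(0), area_um2 = double(0),
    equiv_diameter_um = double(0),
    mean_nuclear = double(0), max_nuclear = double(0),
    mean_ck = double(0), max_ck = double(0),
    mean_cd45 = double(0), max_cd45 = double(0),
    mean_marker = double(0), max_marker = double(0),
    nuclear_overlap = double(0), nc_ratio = double(0),
    n_nuclear_components = integer(0), cd45_correlation = double(0),
    nuc_pos = logical(0), ck_pos = logical(0), cd45_pos = logical(0),
    marker_pos = logical(0), candidate = logical(0),
    label = character(0), rejected_by = character(0),
    tile_row = integer(0), tile_col = integer(0),
    slide_x_um = double(0), slide_y_um = double(0))
}

#' Scan a whole slide
#'
#' Applies [scan_tile()] to every tile, assigns stable object ids, merges
#' duplicate detections from tile overlaps and builds the retrieval
#' picklist. The result is fully determined by the tiles and parameters (a
#' single-process, per-tile loop with deterministic object ordering).
#'
#' @param tiles List of [tile_image()]s covering the slide.
#' @param layout A [slide_layout()].
#' @param rules A [rule_config()].
#' @param k Threshold multiplier.
#' @param min_area_um2,max_area_um2 Segmentation area gate.
#' @param dedup_radius_um Cross-tile merge radius (see
#'   [dedup_detections()]).
#' @param shifts Optional chromatic shifts to compensate on every tile.
#'
#' @return A `slide_scan` object: list with `detections` (deduplicated),
#'   `raw_detections`, `picklist`, `summary` (named counts), `layout`,
#'   `rules`, `k`.
#' @export
scan_slide <- function(tiles, layout, rules = rule_config(), k = 6,
                       min_area_um2 = 20, max_area_um2 = 2000,
                       dedup_radius_um = 15, shifts = NULL) {
  raw <- purrr::map(tiles, scan_tile, layout = layout, rules = rules, k = k,
                    min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                    shifts = shifts)
  raw <- dplyr::bind_rows(raw)
  raw <- dplyr::mutate(raw, object_id = dplyr::row_number(), .before = 1)
  uniq <- dedup_detections(raw, layout, radius_um = dedup_radius_um)
  picklist <- build_picklist(uniq, layout)
  summary <- list(
    n_tiles = length(tiles),
    n_objects_raw = nrow(raw),
    n_unique = nrow(uniq),
    n_candidates = sum(uniq$candidate),
    n_cell = sum(uniq$label == "CELL"),
    n_indeterminate = sum(uniq$label == "INDETERMINATE"),
    n_not_a_cell = sum(uniq$label == "NOT_A_CELL"))
  structure(list(detections = uniq, raw_detections = raw,
                 picklist = picklist, summary = summary, layout = layout,
                 rules = rules, k = k),
            class = "slide_scan")
}

#' @export
print.slide_scan <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<slide_scan> %d tiles: %d objects (%d unique), %d candidates\n",
    s$n_tiles, s$n_objects_raw, s$n_unique, s$n_candidates))
  cat(sprintf("  CELL %d | INDETERMINATE %d | NOT_A_CELL %d\n",
              s$n_cell, s$n_indeterminate, s$n_not_a_cell))
  invisible(x)
}

#' @describeIn scan_slide Deduplicated detection table of a scan.
#' @param x A `slide_scan`.
#' @param ... Unused.
#' @method tidy slide_scan
#' @export
tidy.slide_scan <- function(x, ...) x$detections

#' @describeIn scan_slide One-row summary of a scan.
#' @method glance slide_scan
#' @export
glance.slide_scan <- function(x, ...) tibble::as_tibble(x$summary)

#' @describeIn scan_slide Slide map of the classified detections.
#' @param object A `slide_scan`.
#' @method autoplot slide_scan
#' @export
autoplot.slide_scan <- function(object, ...) {
  det <- object$detections
  ggplot2::ggplot(det,
                  ggplot2::aes(x = .data$slide_x_um, y = .data$slide_y_um,
                               colour = .data$label,
                               shape = .data$candidate)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_colour_manual(
      values = c(CELL = "#1b9e77", INDETERMINATE = "#7570b3",
                 NOT_A_CELL = "#d95f02"),
      drop = FALSE) +
    ggplot2::labs(x = "slide x (µm)", y = "slide y (µm)",
                  colour = "label", shape = "candidate",
                  title = "Classified detections") +
    ggplot2::theme_minimal()
}

#' Plot one channel of a tile with detection outlines
#'
#' @param tile A [tile_image()].
#' @param channel Channel name to display.
#' @param detections Optional detection tibble (same tile) whose centroids
#'   are marked.
#'
#' @return A ggplot object.
#' @export
plot_tile <- function(tile, channel = "ck", detections = NULL) {
  p <- tile$planes[[channel]]
  df <- tidyr::expand_grid(y = seq_len(nrow(p)) - 1,
                           x = seq_len(ncol(p)) - 1)
  df$intensity <- as.vector(t(p))
  g <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                        fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("tile (%d,%d) — %s",
                                  tile$row, tile$col, channel)) +
    ggplot2::theme_minimal()
  if (!is.null(detections) && nrow(detections) > 0) {
    g <- g + ggplot2::geom_point(
      data = detections,
      ggplot2::aes(x = .data$centroid_px_x, y = .data$centroid_px_y),
      inherit.aes = FALSE, colour = "red", shape = 1, size = 4)
  }
  g
}
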