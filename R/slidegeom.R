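# Tile-grid geometry: the slide is covered by a grid_rows x grid_cols grid of
# square camera fields of view (tiles). Adjacent tiles overlap by overlap_um on
# all sides so a cell on a tile border is imaged whole in at least one tile.

#' Tile-grid slide layout
#'
#' Describes the tiling geometry of a scanned slide: tile size in pixels,
#' micrometres per pixel, and the overlap between adjacent fields of view.
#' Tile `(r, c)` (0-based) has its top-left pixel at slide position
#' `(c * stride_um, r * stride_um)` where
#' `stride_um = tile_px * pixel_pitch - overlap_um`.
#'
#' @param grid_rows,grid_cols Number of tile rows / columns (positive integers).
#' @param tile_px Tile edge length in pixels.
#' @param pixel_pitch Micrometres per pixel.
#' @param overlap_um Overlap between adjacent tiles in micrometres; must be
#'   smaller than the tile extent `tile_px * pixel_pitch`.
#' @param channels Ordered channel names.
#'
#' @return A `slide_layout` object (list with the fields above plus the
#'   derived `stride_um`, `width_um`, `height_um`).
#' @export
slide_layout <- function(grid_rows, grid_cols, tile_px,
                         pixel_pitch = 0.65, overlap_um = 50,
                         channels = CHANNELS) {
  stopifnot(grid_rows >= 1, grid_cols >= 1, tile_px >= 1,
            pixel_pitch > 0, overlap_um >= 0)
  extent <- tile_px * pixel_pitch
  if (overlap_um >= extent) {
    abort(sprintf(
      "invalid layout: overlap_um (%g) must be < tile extent (%g um)",
      overlap_um, extent), class = "ctcscan_config_error")
  }
  stride <- extent - overlap_um
  structure(list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    tile_px = as.integer(tile_px), pixel_pitch = pixel_pitch,
    overlap_um = overlap_um, stride_um = stride,
    width_um  = (grid_cols - 1) * stride + extent,
    height_um = (grid_rows - 1) * stride + extent,
    channels = channels
  ), class = "slide_layout")
}

#' @export
print.slide_layout <- function(x, ...) {
  cat(sprintf(
    "<slide_layout> %d x %d tiles of %d px (%.2f um/px), overlap %g um\n",
    x$grid_rows, x$grid_cols, x$tile_px, x$pixel_pitch, x$overlap_um))
  cat(sprintf("  slide extent %.1f x %.1f um, stride %.1f um\n",
              x$width_um, x$height_um, x$stride_um))
  invisible(x)
}

#' Map tile-local pixel coordinates to slide coordinates
#'
#' Pixel indices are 0-based with `x` along columns and `y` along rows; pixel
#' `(0, 0)` of tile `(0, 0)` sits at slide position `(0, 0)` micrometres.
#'
#' @param tile_row,tile_col 0-based tile grid indices (vectorised).
#' @param px_x,px_y 0-based (possibly fractional) pixel coordinates.
#' @param layout A [slide_layout()].
#'
#' @return A tibble with columns `x_um`, `y_um`.
#' @export
tile_to_slide <- function(tile_row, tile_col, px_x, px_y, layout) {
  tibble::tibble(
    x_um = tile_col * layout$stride_um + px_x * layout$pixel_pitch,
    y_um = tile_row * layout$stride_um + px_y * layout$pixel_pitch
  )
}

#' Map slide coordinates back to a tile and pixel position
#'
#' Inverse of [tile_to_slide()]. In overlap regions a point lies in more than
#' one tile; the tile with the largest margin to its field-of-view border is
#' returned, so the round trip through [tile_to_slide()] is exact up to the
#' tile choice.
#'
#' @param x_um,y_um Slide coordinates in micrometres (vectorised).
#' @param layout A [slide_layout()].
#'
#' @return A tibble with columns `tile_row`, `tile_col`, `px_x`, `px_y`.
#' @export
slide_to_tile <- function(x_um, y_um, layout) {
  pick <- function(pos, n_tiles) {
    lo <- pmin(pmax(floor(pos / layout$stride_um), 0), n_tiles - 1)
    # candidate lo and lo-1 both contain the point inside overlap strips;
    # choose the larger distance to the nearest tile edge
    cand <- function(idx) {
      px <- (pos - idx * layout$stride_um) / layout$pixel_pitch
      ok <- idx >= 0 & px >= 0 & px < layout$tile_px
      margin <- pmin(px, layout$tile_px - 1 - px)
      margin[!ok] <- -Inf
      list(idx = idx, px = px, margin = margin)
    }
    a <- cand(lo); b <- cand(lo - 1)
    use_b <- b$margin > a$margin
    list(idx = ifelse(use_b, b$idx, a$idx), px = ifelse(use_b, b$px, a$px))
  }
  cx <- pick(x_um, layout$grid_cols)
  cy <- pick(y_um, layout$grid_rows)
  tibble::tibble(tile_row = as.integer(cy$idx), tile_col = as.integer(cx$idx),
                 px_x = cx$px, px_y = cy$px)
}

# distance (um) from a tile-local pixel position to the closest FOV border
border_margin_um <- function(px_x, px_y, layout) {
  pmin(px_x, px_y, layout$tile_px - 1 - px_x, layout$tile_px - 1 - px_y) *
    layout$pixel_pitch
}

#' Merge duplicate detections from overlapping tiles
#'
#' Tiles overlap, so one physical cell can be detected in up to four adjacent
#' tiles. Detections are grouped by single-linkage clustering of their slide
#' coordinates at `radius_um`; each group is reduced to the member whose
#' centroid lies farthest from its own tile's border (the least truncated
#' copy), with ties broken by `object_id`.
#'
#' @param detections A detection tibble with at least `object_id`,
#'   `tile_row`, `tile_col`, `centroid_px_x`, `centroid_px_y`, `slide_x_um`,
#'   `slide_y_um`.
#' @param layout A [slide_layout()].
#' @param radius_um Single-linkage merge radius in micrometres.
#'
#' @return The representative rows, one per group, with a `group_size` column.
#' @export
dedup_detections <- function(detections, layout, radius_um = 15) {
  # group_size accumulates across applications, so dedup is idempotent
  if (!"group_size" %in% names(detections)) {
    detections$group_size <- rep(1L, nrow(detections))
  }
  if (nrow(detections) <= 1) return(detections)
  grp <- cutree(hclust(dist(cbind(detections$slide_x_um,
                                  detections$slide_y_um)),
                       method = "single"),
                h = radius_um)
  detections |>
    dplyr::mutate(
      .group = grp,
      .margin = border_margin_um(.data$centroid_px_x, .data$centroid_px_y,
                                 layout)) |>
    dplyr::group_by(.data$.group) |>
    dplyr::mutate(group_size = sum(.data$group_size)) |>
    dplyr::arrange(dplyr::desc(.data$.margin), .data$object_id,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$object_id) |>
    dplyr::select(-".group", -".margin")
}

#' Build a retrieval picklist from classified detections
#'
#' Keeps only detections labelled `CELL` and orders them in a serpentine
#' pattern (horizontal bands by slide `y`, alternating scan direction in `x`)
#' to minimise stage travel between single-cell retrievals. The order is a
#' pure function of the coordinates, so it is stable under permutation of the
#' input rows.
#'
#' @param detections Deduplicated detection tibble with `label` column.
#' @param layout A [slide_layout()].
#' @param band_um Band height in micrometres; defaults to the tile stride.
#'
#' @return A tibble `cell_id`, `slide_x_um`, `slide_y_um`, `label`,
#'   `tile_row`, `tile_col` in visiting order.
#' @export
build_picklist <- function(detections, layout, band_um = NULL) {
  band_um <- band_um %||% layout$stride_um
  cells <- dplyr::filter(detections, .data$label == "CELL")
  if (nrow(cells) == 0) {
    return(tibble::tibble(cell_id = integer(0), slide_x_um = double(0),
                          slide_y_um = double(0), label = character(0),
                          tile_row = integer(0), tile_col = integer(0)))
  }
  cells |>
    dplyr::mutate(.band = floor(.data$slide_y_um / band_um),
                  .xkey = ifelse(.data$.band %% 2 == 0, .data$slide_x_um,
                                 -.data$slide_x_um)) |>
    dplyr::arrange(.data$.band, .data$.xkey, .data$slide_y_um,
                   .data$object_id) |>
    dplyr::transmute(cell_id = .data$object_id,
                     slide_x_um = .data$slide_x_um,
                     slide_y_um = .data$slide_y_um,
                     label = .data$label,
                     tile_row = .data$tile_row, tile_col = .data$tile_col)
}
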