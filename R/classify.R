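# Rule-based classification of segmented cytokeratin objects into
# Cell / Indeterminate / Not-a-Cell. The "candidate" flag marks objects that
# meet the presentation criteria (CK+, nucleated, CD45-) independently of
# the final morphology gate, mirroring the distinction between objects
# presented for review and objects confirmed as tumor cells.

#' Classification rule configuration
#'
#' All cutoffs of the decision table, exposed so they can be changed without
#' code changes. Ties at a threshold resolve to positive (`>=`).
#'
#' @param corr_reject_r CD45-correlation cutoff above which a CD45-positive
#'   object is rejected outright as an artifact (default 0.5).
#' @param min_nuclear_overlap Minimum fraction of the object covered by
#'   supra-threshold nuclear stain to count as nucleated.
#' @param max_area_um2_cell Morphology gate: maximum area of a single
#'   confirmed cell; larger candidates (e.g. squamous contaminants) are
#'   rejected.
#' @param min_nc_ratio Morphology gate: minimum nuclear:cytoplasm area
#'   ratio of a confirmed cell.
#' @param thresholds Optional named list of per-channel positivity-threshold
#'   overrides (`ck`, `cd45`, `marker`); by default the per-tile adaptive
#'   thresholds are used.
#'
#' @return A `rule_config` object.
#' @export
rule_config <- function(corr_reject_r = 0.5, min_nuclear_overlap = 0.2,
                        max_area_um2_cell = 700, min_nc_ratio = 0.15,
                        thresholds = list()) {
  stopifnot(corr_reject_r > 0, corr_reject_r <= 1,
            min_nuclear_overlap >= 0, min_nuclear_overlap <= 1,
            max_area_um2_cell > 0, min_nc_ratio >= 0, min_nc_ratio <= 1)
  structure(list(corr_reject_r = corr_reject_r,
                 min_nuclear_overlap = min_nuclear_overlap,
                 max_area_um2_cell = max_area_um2_cell,
                 min_nc_ratio = min_nc_ratio,
                 thresholds = thresholds),
            class = "rule_config")
}

#' @export
print.rule_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<rule_config> corr_reject_r %.2f, min_nuclear_overlap %.2f,\n",
    "  morphology gate: area <= %g um^2 and nc_ratio >= %.2f\n"),
    x$corr_reject_r, x$min_nuclear_overlap, x$max_area_um2_cell,
    x$min_nc_ratio))
  invisible(x)
}

resolve_thresholds <- function(rules, models) {
  get1 <- function(ch) {
    rules$thresholds[[ch]] %||% models[[ch]]$threshold %||%
      abort(sprintf("no positivity threshold available for channel '%s'", ch),
            class = "ctcscan_config_error")
  }
  list(ck = get1("ck"), cd45 = get1("cd45"), marker = get1("marker"))
}

#' Per-channel positivity calls for detected objects
#'
#' An object is positive for a channel when its mean intensity over the mask
#' is at or above that channel's threshold; it is nucleated when its nuclear
#' overlap fraction is at or above `min_nuclear_overlap`.
#'
#' @param features Feature tibble from [extract_features()] (one or more
#'   rows).
#' @param rules A [rule_config()].
#' @param models Named list of per-channel `threshold_model`s (used unless
#'   overridden in `rules$thresholds`).
#'
#' @return `features` with logical columns `nuc_pos`, `ck_pos`, `cd45_pos`,
#'   `marker_pos` added.
#' @export
call_positivity <- function(features, rules, models = list()) {
  thr <- resolve_thresholds(rules, models)
  dplyr::mutate(
    features,
    nuc_pos = .data$nuclear_overlap >= rules$min_nuclear_overlap,
    ck_pos = .data$mean_ck >= thr$ck,
    cd45_pos = .data$mean_cd45 >= thr$cd45,
    marker_pos = .data$mean_marker >= thr$marker)
}

#' Classify detected objects
#'
#' Deterministic decision table, evaluated in order for each object:
#'
#' 1. CD45 correlation at or above `corr_reject_r` *and* CD45-positive:
#'    `NOT_A_CELL`, rejected as a correlation artifact; never a candidate.
#' 2. CK-positive, nucleated, CD45-negative: a *candidate*. It is a `CELL`
#'    if the morphology gate passes (area at most `max_area_um2_cell` and
#'    nuclear:cytoplasm ratio at least `min_nc_ratio`), otherwise
#'    `NOT_A_CELL` rejected by morphology (the squamous-contaminant path).
#' 3. CK-positive and CD45-positive (below the correlation cutoff):
#'    `INDETERMINATE` (signal in the exclusionary channel).
#' 4. CK-positive, not nucleated, marker-positive: `INDETERMINATE`.
#' 5. Everything else: `NOT_A_CELL`.
#'
#' The auxiliary marker channel (EpCAM/EGFR/Ki-67) is interpretive only and
#' never vetoes a `CELL` call.
#'
#' @param features Feature tibble from [extract_features()].
#' @param rules A [rule_config()].
#' @param models Per-channel `threshold_model`s as in [call_positivity()].
#'
#' @return `features` with `nuc_pos`/`ck_pos`/`cd45_pos`/`marker_pos`,
#'   `candidate` (logical), `label` and `rejected_by` columns added.
#' @export
classify_objects <- function(features, rules, models = list()) {
  f <- call_positivity(features, rules, models)
  high_corr <- f$cd45_correlation >= rules$corr_reject_r & f$cd45_pos
  candidate <- !high_corr & f$ck_pos & f$nuc_pos & !f$cd45_pos
  morph_ok <- f$area_um2 <= rules$max_area_um2_cell &
    f$nc_ratio >= rules$min_nc_ratio
  label <- dplyr::case_when(
    high_corr ~ "NOT_A_CELL",
    candidate & morph_ok ~ "CELL",
    candidate ~ "NOT_A_CELL",
    f$ck_pos & f$cd45_pos ~ "INDETERMINATE",
    f$ck_pos & !f$nuc_pos & f$marker_pos ~ "INDETERMINATE",
    .default = "NOT_A_CELL")
  rejected_by <- dplyr::case_when(
    high_corr ~ "cd45_correlation",
    candidate & !morph_ok ~ "morphology",
    .default = "none")
  dplyr::mutate(f, candidate = candidate, label = label,
                rejected_by = rejected_by)
}

#' Extract a fixed-size review glyph for a detection
#'
#' Crops a `size x size` pixel box per channel, centred on the rounded
#' centroid. Regions falling outside the tile are zero-padded so every glyph
#' has exactly the same dimensions; the padding offset is recorded.
#'
#' @param tile A [tile_image()].
#' @param centroid_px `c(x, y)` 0-based centroid in tile pixels.
#' @param size Glyph edge length in pixels (default 200).
#'
#' @return A `glyph` list: `planes` (named list of `size x size` matrices),
#'   `centroid_px`, `offset_px` (`c(x, y)` tile position of the glyph's
#'   top-left pixel, may be negative when padded).
#' @export
make_glyph <- function(tile, centroid_px, size = 200) {
  cx <- round(centroid_px[1]); cy <- round(centroid_px[2])
  half <- size %/% 2
  x0 <- cx - half; y0 <- cy - half            # 0-based tile coords of crop
  d <- dim(tile$planes[[1]])
  planes <- lapply(tile$planes, function(p) {
    g <- matrix(0, size, size)
    src_r <- max(0, y0):min(d[1] - 1, y0 + size - 1)
    src_c <- max(0, x0):min(d[2] - 1, x0 + size - 1)
    if (length(src_r) > 0 && length(src_c) > 0 &&
        src_r[1] <= src_r[length(src_r)] && src_c[1] <= src_c[length(src_c)]) {
      g[src_r - y0 + 1, src_c - x0 + 1] <- p[src_r + 1, src_c + 1]
    }
    g
  })
  structure(list(planes = planes, centroid_px = c(cx, cy),
                 offset_px = c(x0, y0)),
            class = "glyph")
}
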