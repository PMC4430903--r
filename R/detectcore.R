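# Per-tile detection: robust adaptive thresholding, cytokeratin-primary
# segmentation into 8-connected hole-filled objects, and per-object feature
# extraction (per-channel intensities, nuclear overlap, CD45 correlation).

#' Adaptive background threshold for one channel plane
#'
#' Robust per-tile background model: the threshold is
#' `median + k * 1.4826 * MAD`, with the median and (unscaled) median
#' absolute deviation computed over the whole tile. The median/MAD pair is
#' insensitive to the sparse bright objects that would bias a mean/SD
#' estimate, and per-tile computation adapts to illumination drift across
#' the slide. A MAD of zero (constant plane) is flagged as degenerate.
#'
#' @param plane Intensity matrix.
#' @param k Multiplier on the scaled MAD (default 6).
#' @param channel Optional channel name recorded in the model.
#'
#' @return A `threshold_model` list: `channel`, `background_median`,
#'   `background_mad` (unscaled), `k`, `threshold`, `degenerate`.
#' @export
estimate_threshold <- function(plane, k = 6, channel = NA_character_) {
  if (length(plane) == 0) {
    abort("cannot estimate a threshold on an empty plane",
          class = "ctcscan_config_error")
  }
  med <- median(plane)
  m <- median(abs(plane - med))
  structure(list(channel = channel, background_median = med,
                 background_mad = m, k = k,
                 threshold = med + k * 1.4826 * m,
                 degenerate = m == 0),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf(
    "<threshold_model> %s: median %.1f, MAD %.1f, k %g -> threshold %.1f%s\n",
    x$channel %||% "?", x$background_median, x$background_mad, x$k,
    x$threshold, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged afterwards with a union-find pass.
label8 <- function(binary) {
  lab <- EBImage::bwlabel(binary)
  n <- max(lab)
  if (n < 2) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # down-right diagonal pairs
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]    # down-left diagonal pairs
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Segment the primary (cytokeratin) channel of a tile
#'
#' Primary detection runs on the cytokeratin channel: pixels strictly above
#' the adaptive threshold are grouped into 8-connected components, holes are
#' filled, and components outside the area gate are discarded. Objects are
#' returned in deterministic row-major order of their bounding-box origin.
#'
#' @param ck_plane Cytokeratin intensity matrix.
#' @param model A [estimate_threshold()] model for this plane.
#' @param pixel_pitch Micrometres per pixel.
#' @param min_area_um2,max_area_um2 Area gate. The lower bound removes
#'   sub-cellular specks; the upper bound is generous so clusters pass,
#'   leaving squamous rejection to the classifier's morphology gate.
#'
#' @return A list of `object_mask` lists with fields `pixels` (linear
#'   indices), `bbox` (`c(row0, col0, row1, col1)`, 0-based), `centroid_px`
#'   (`c(x, y)`, 0-based sub-pixel), `area_px`, `area_um2`.
#' @export
segment_primary <- function(ck_plane, model, pixel_pitch,
                            min_area_um2 = 20, max_area_um2 = 2000) {
  binary <- ck_plane > model$threshold
  if (!any(binary)) return(list())
  filled <- as.matrix(EBImage::fillHull(matrix(as.integer(binary),
                                               nrow(ck_plane))))
  lab <- label8(filled)
  n <- max(lab)
  if (n == 0) return(list())
  px_area <- pixel_pitch^2
  idx <- which(lab > 0)
  labs <- lab[idx]
  rows <- ((idx - 1) %% nrow(lab)) + 1
  cols <- ((idx - 1) %/% nrow(lab)) + 1
  masks <- lapply(seq_len(n), function(i) {
    sel <- labs == i
    area_px <- sum(sel)
    area_um2 <- area_px * px_area
    if (area_um2 < min_area_um2 || area_um2 > max_area_um2) return(NULL)
    rr <- rows[sel]; cc <- cols[sel]
    list(pixels = idx[sel],
         bbox = c(min(rr) - 1, min(cc) - 1, max(rr) - 1, max(cc) - 1),
         centroid_px = c(mean(cc) - 1, mean(rr) - 1),
         area_px = area_px, area_um2 = area_um2)
  })
  masks <- masks[!vapply(masks, is.null, logical(1))]
  if (length(masks) == 0) return(masks)
  ord <- order(vapply(masks, function(m) m$bbox[1], numeric(1)),
               vapply(masks, function(m) m$bbox[2], numeric(1)))
  masks[ord]
}

#' Fraction of an object covered by nuclear stain
#'
#' The fraction of mask pixels whose nuclear-channel intensity is strictly
#' above the nuclear threshold; operationalizes the "positive nuclear stain"
#' criterion.
#'
#' @param mask An object mask from [segment_primary()].
#' @param nuclear_plane Nuclear-channel intensity matrix.
#' @param nuclear_model [estimate_threshold()] model for the nuclear plane.
#'
#' @return A fraction in `[0, 1]`.
#' @export
nuclear_overlap <- function(mask, nuclear_plane, nuclear_model) {
  mean(nuclear_plane[mask$pixels] > nuclear_model$threshold)
}

# dilate a mask by `by` pixels (disc) within a local window; returns linear
# indices into the full plane
dilate_mask <- function(mask, dims, by = 2) {
  nr <- dims[1]
  r0 <- max(1, mask$bbox[1] + 1 - by); r1 <- min(dims[1], mask$bbox[3] + 1 + by)
  c0 <- max(1, mask$bbox[2] + 1 - by); c1 <- min(dims[2], mask$bbox[4] + 1 + by)
  win <- matrix(0L, r1 - r0 + 1, c1 - c0 + 1)
  rows <- ((mask$pixels - 1) %% nr) + 1
  cols <- ((mask$pixels - 1) %/% nr) + 1
  win[cbind(rows - r0 + 1, cols - c0 + 1)] <- 1L
  dil <- as.matrix(EBImage::dilate(win, EBImage::makeBrush(2 * by + 1,
                                                           shape = "disc")))
  wi <- which(dil > 0)
  wr <- ((wi - 1) %% nrow(win)) + r0
  wc <- ((wi - 1) %/% nrow(win)) + c0
  (wc - 1) * nr + wr
}

#' Cytokeratin/CD45 correlation of an object
#'
#' Pearson correlation of cytokeratin vs CD45 intensity over the object mask
#' dilated by 2 pixels (the dilation captures membrane CD45 ringing a
#' cytokeratin-positive object). CD45 is the exclusionary leukocyte marker:
#' a high correlation means the cytokeratin object itself carries CD45 and
#' is an artifact, not a tumor cell. If either channel is constant over the
#' footprint the correlation is defined as 0.
#'
#' @param mask An object mask from [segment_primary()].
#' @param ck_plane,cd45_plane Channel intensity matrices.
#' @param dilate_px Dilation radius in pixels.
#'
#' @return Pearson r in `[-1, 1]`.
#' @export
cd45_correlation <- function(mask, ck_plane, cd45_plane, dilate_px = 2) {
  if (length(mask$pixels) == 0) {
    abort("cd45_correlation needs a non-empty mask",
          class = "ctcscan_config_error")
  }
  fp <- dilate_mask(mask, dim(ck_plane), by = dilate_px)
  a <- ck_plane[fp]; b <- cd45_plane[fp]
  if (length(fp) < 2 || sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

#' Extract per-object features from a tile
#'
#' Populates everything the classifier needs: per-channel mean and max over
#' the mask, area, equivalent diameter, nuclear overlap fraction, the
#' nuclear:cytoplasm area ratio (nuclear supra-threshold pixel count within
#' the mask over mask area), the CD45 correlation, and the number of
#' distinct nuclear components inside the mask (an auxiliary count useful
#' for clusters, reported but not used for classification).
#'
#' @param tile A [tile_image()].
#' @param mask An object mask from [segment_primary()].
#' @param models Named list of `threshold_model`s, one per channel
#'   (including `nuclear`).
#'
#' @return A one-row tibble of features.
#' @export
extract_features <- function(tile, mask, models) {
  px <- mask$pixels
  stats <- lapply(CHANNELS, function(ch) {
    v <- tile$planes[[ch]][px]
    tibble::tibble("mean_{ch}" := mean(v), "max_{ch}" := max(v))
  })
  nuc_supra <- tile$planes$nuclear[px] > models$nuclear$threshold
  frac <- mean(nuc_supra)
  # count nuclear components inside the mask (auxiliary, for clusters)
  n_nuc <- 0L
  if (any(nuc_supra)) {
    nr <- nrow(tile$planes$nuclear)
    sub <- matrix(0L,
                  mask$bbox[3] - mask$bbox[1] + 1,
                  mask$bbox[4] - mask$bbox[2] + 1)
    rows <- ((px - 1) %% nr) - mask$bbox[1] + 1
    cols <- ((px - 1) %/% nr) - mask$bbox[2] + 1
    sub[cbind(rows, cols)[nuc_supra, , drop = FALSE]] <- 1L
    n_nuc <- max(label8(sub))
  }
  dplyr::bind_cols(
    tibble::tibble(
      centroid_px_x = mask$centroid_px[1], centroid_px_y = mask$centroid_px[2],
      area_px = mask$area_px, area_um2 = mask$area_um2,
      equiv_diameter_um = 2 * sqrt(mask$area_um2 / pi)),
    dplyr::bind_cols(stats),
    tibble::tibble(
      nuclear_overlap = frac,
      nc_ratio = frac,
      n_nuclear_components = n_nuc,
      cd45_correlation = cd45_correlation(mask, tile$planes$ck,
                                          tile$planes$cd45)))
}

#' Estimate chromatic shifts from a calibration tile
#'
#' Cross-correlates each channel against the reference channel (FFT-based,
#' with parabolic sub-pixel refinement of the correlation peak). The
#' returned `(dx, dy)` is the shift of the channel's content relative to the
#' reference; applying the negated shift with [apply_chromatic_shift()]
#' co-registers the channels.
#'
#' @param tile A [tile_image()] with shared structure across channels
#'   (e.g. from [simulate_beads()]).
#' @param reference Reference channel name.
#'
#' @return A tibble `channel`, `dx`, `dy` for the non-reference channels.
#' @export
register_channels <- function(tile, reference = "nuclear") {
  ref <- tile$planes[[reference]]
  if (sd(ref) == 0) {
    abort("calibration tile has no structure in the reference channel",
          class = "ctcscan_calibration_error")
  }
  a <- ref - mean(ref)
  fa <- fft(a)
  nr <- nrow(a); nc <- ncol(a)
  refine <- function(cm1, c0, cp1) {
    den <- cm1 - 2 * c0 + cp1
    if (den == 0) 0 else 0.5 * (cm1 - cp1) / den
  }
  res <- lapply(setdiff(names(tile$planes), reference), function(ch) {
    b <- tile$planes[[ch]]
    if (sd(b) == 0) {
      abort(sprintf("calibration tile is flat in channel '%s'", ch),
            class = "ctcscan_calibration_error")
    }
    cc <- Re(fft(Conj(fa) * fft(b - mean(b)), inverse = TRUE)) / (nr * nc)
    p <- which.max(cc)
    pr <- ((p - 1) %% nr) + 1
    pc <- ((p - 1) %/% nr) + 1
    wrap <- function(i, n) ((i - 1) %% n) + 1
    dy <- (pr - 1) + refine(cc[wrap(pr - 1, nr), pc], cc[pr, pc],
                            cc[wrap(pr + 1, nr), pc])
    dx <- (pc - 1) + refine(cc[pr, wrap(pc - 1, nc)], cc[pr, pc],
                            cc[pr, wrap(pc + 1, nc)])
    if (dy > nr / 2) dy <- dy - nr
    if (dx > nc / 2) dx <- dx - nc
    tibble::tibble(channel = ch, dx = dx, dy = dy)
  })
  dplyr::bind_rows(res)
}
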