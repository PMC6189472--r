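# Spot and cell segmentation, mask combination.

#' Mask set for spot/cell enrichment analysis
#'
#' Bundle of the masks the enrichment analysis operates on: a binary spot
#' mask, a labeled cell mask (integer id per cell, 0 = background) and the
#' per-cell partition into on-spot (`cell` intersected with `spots`) and
#' off-spot (`cell` minus `spots`) labeled masks. For every label, on-spot
#' and off-spot are disjoint and their union is the cell.
#'
#' @param spots Logical matrix (binary spot mask).
#' @param cells Integer matrix (labeled cell mask).
#' @return A `mask_set` object with elements `spots`, `cells`, `on_spot`,
#'   `off_spot`.
#' @export
mask_set <- function(spots, cells) {
  stopifnot(all(dim(spots) == dim(cells)))
  spots <- spots > 0
  cells <- structure(as.integer(cells), dim = dim(cells))
  on_spot <- cells; on_spot[!spots] <- 0L
  off_spot <- cells; off_spot[spots] <- 0L
  structure(list(spots = spots, cells = cells,
                 on_spot = on_spot, off_spot = off_spot),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("<mask_set> %dx%d px, %d cell(s), %d spot px\n",
              nrow(x$cells), ncol(x$cells),
              length(setdiff(unique(as.vector(x$cells)), 0L)), sum(x$spots)))
  invisible(x)
}

#' Segment antibody spots by intensity threshold
#'
#' Thresholds the spot channel (Otsu by default, or a fixed threshold),
#' fills holes, and — when the nominal spot diameter is known — removes
#' objects smaller than 25% of the nominal spot area.
#'
#' @param spot_channel 2-D numeric matrix (the spot channel).
#' @param threshold Optional fixed threshold; pixels `>= threshold` are spot.
#'   When absent, Otsu's threshold is used.
#' @param spot_diameter_px Optional nominal spot diameter in pixels, enabling
#'   the small-object filter.
#' @return Logical matrix. An all-background image yields an empty mask with
#'   a warning.
#' @export
segment_spots <- function(spot_channel, threshold = NULL, spot_diameter_px = NULL) {
  stopifnot(is.matrix(spot_channel))
  if (is.null(threshold)) {
    threshold <- tryCatch(otsu_threshold(spot_channel), error = function(e) NULL)
    if (is.null(threshold)) {
      warn("Spot channel is constant; returning an empty spot mask.")
      return(matrix(FALSE, nrow(spot_channel), ncol(spot_channel)))
    }
  }
  mask <- spot_channel >= threshold
  if (!any(mask) || all(mask)) {
    if (all(mask)) mask[] <- FALSE
    warn("No spots found above threshold; spot mask is empty.")
    return(mask)
  }
  mask <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0
  mask <- matrix(as.logical(mask), nrow(spot_channel), ncol(spot_channel))
  if (!is.null(spot_diameter_px)) {
    min_area <- 0.25 * pi * (spot_diameter_px / 2)^2
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    sizes <- table(lab[lab > 0])
    drop <- as.integer(names(sizes)[sizes < min_area])
    mask[matrix(as.integer(lab), nrow(mask)) %in% drop] <- FALSE
  }
  mask
}

#' Segment cells from a DIC image
#'
#' Edge-based segmentation: Sobel gradient magnitude, hysteresis threshold
#' (components of the low mask are kept iff they contain a high-threshold
#' pixel), morphological closing, hole filling, connected components, and a
#' size filter. Filled components are eroded by the closing radius so the
#' recovered outline tracks the DIC edge ridge rather than its dilation.
#'
#' @param dic_channel 2-D numeric matrix (DIC/brightfield image).
#' @param min_area_px Discard components smaller than this (pixels).
#' @param closing_radius Disc radius (px) for morphological closing.
#' @param high,low Hysteresis thresholds on gradient magnitude. Defaults:
#'   `high` = Otsu of the gradient image, `low = 0.4 * high`.
#' @return Integer matrix labeling each surviving cell (0 = background).
#'   Empty labeling with a warning when nothing survives.
#' @export
segment_cells <- function(dic_channel, min_area_px = 200L, closing_radius = 2L,
                          high = NULL, low = NULL) {
  stopifnot(is.matrix(dic_channel))
  empty <- matrix(0L, nrow(dic_channel), ncol(dic_channel))
  grad <- sobel_magnitude(dic_channel)
  high <- high %||% tryCatch(otsu_threshold(grad), error = function(e) NULL)
  if (is.null(high) || max(grad) == 0) {
    warn("No edges found in the DIC image; returning an empty labeling.")
    return(empty)
  }
  low <- low %||% (0.4 * high)
  low_mask <- grad >= low
  lab_low <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(low_mask * 1))),
                    nrow(dic_channel))
  keep <- unique(lab_low[grad >= high & lab_low > 0])
  edges <- lab_low %in% keep & lab_low > 0
  dim(edges) <- dim(dic_channel)
  if (!any(edges)) {
    warn("Hysteresis threshold removed all edges; returning an empty labeling.")
    return(empty)
  }
  brush <- EBImage::makeBrush(2L * closing_radius + 1L, shape = "disc")
  closed <- EBImage::closing(EBImage::Image(edges * 1), brush)
  filled <- EBImage::fillHull(closed)
  eroded <- EBImage::erode(filled, brush)
  lab <- matrix(as.integer(EBImage::bwlabel(eroded > 0)), nrow(dic_channel))
  sizes <- table(lab[lab > 0])
  keep_ids <- as.integer(names(sizes)[sizes >= min_area_px])
  if (!length(keep_ids)) {
    warn("No component survived the size filter; returning an empty labeling.")
    return(empty)
  }
  out <- empty
  for (i in seq_along(keep_ids)) out[lab == keep_ids[i]] <- i
  out
}

sobel_magnitude <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE)
  ky <- t(kx)
  gx <- as.matrix(EBImage::filter2(EBImage::Image(img), kx))
  gy <- as.matrix(EBImage::filter2(EBImage::Image(img), ky))
  sqrt(gx^2 + gy^2)
}

#' Combine spot and cell segmentations
#'
#' Partitions every cell into its on-spot and off-spot parts — the masks the
#' enrichment ratio is computed over.
#'
#' @param spots Logical spot mask.
#' @param cells Labeled cell mask (same shape).
#' @return A [mask_set()].
#' @export
combine_masks <- function(spots, cells) {
  if (!all(dim(spots) == dim(cells))) abort("`spots` and `cells` shapes differ.")
  mask_set(spots = spots, cells = cells)
}
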