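# Enrichment ratios on micropatterned spots and at cell-bead contacts.

#' Per-cell spot enrichment ratio
#'
#' For every cell in the mask set, the ratio of the mean background-subtracted
#' fluorescence over the cell's on-spot pixels to that over its off-spot
#' pixels. A ratio of 1 indicates no recruitment; values above / below 1
#' indicate recruitment to / exclusion from the spots. Cells whose on- or
#' off-spot region is smaller than `min_pixels` are excluded (reported with
#' `excluded = TRUE`), and cells whose off-spot mean does not exceed the
#' background are flagged with an undefined ratio.
#'
#' @param fluor_channel 2-D numeric matrix (fluorescence channel).
#' @param masks A [mask_set()] from [combine_masks()].
#' @param background Scalar background level subtracted before the ratio.
#' @param min_pixels Minimum on-spot and off-spot pixel count per cell.
#' @return A tibble with one row per cell: `cell_id`, `ratio`, `mean_on`,
#'   `mean_off` (background-subtracted), `n_pixels_on`, `n_pixels_off`,
#'   `excluded`, `flag`.
#' @export
spot_enrichment <- function(fluor_channel, masks, background = 0, min_pixels = 20L) {
  stopifnot(inherits(masks, "mask_set"),
            all(dim(fluor_channel) == dim(masks$cells)))
  ids <- setdiff(sort(unique(as.vector(masks$cells))), 0L)
  rows <- lapply(ids, function(id) {
    on <- fluor_channel[masks$on_spot == id]
    off <- fluor_channel[masks$off_spot == id]
    n_on <- length(on); n_off <- length(off)
    mean_on <- if (n_on) mean(on) - background else NA_real_
    mean_off <- if (n_off) mean(off) - background else NA_real_
    excluded <- n_on < min_pixels || n_off < min_pixels
    flag <- NA_character_
    ratio <- NA_real_
    if (excluded) {
      flag <- "region_below_min_pixels"
    } else if (mean_off <= 0) {
      flag <- "off_spot_at_or_below_background"
    } else {
      ratio <- mean_on / mean_off
    }
    tibble(cell_id = id, ratio = ratio, mean_on = mean_on, mean_off = mean_off,
           n_pixels_on = n_on, n_pixels_off = n_off,
           excluded = excluded, flag = flag)
  })
  bind_rows(rows)
}

#' Bead-contact enrichment ratio
#'
#' Ratio of the mean background-subtracted fluorescence in a membrane ROI at
#' the cell-bead contact to that in an equal-sized ROI on the opposite side
#' of the cell. ROI pixel counts differing by more than 10% trigger a
#' warning (the two ROIs should be matched in size).
#'
#' @param fluor_channel 2-D numeric matrix.
#' @param contact,opposite Rasterizable [roi]s over the two membrane regions.
#' @param background Scalar background level.
#' @return A one-row tibble: `ratio`, `mean_contact`, `mean_opposite`
#'   (background-subtracted), `n_contact`, `n_opposite`.
#' @export
bead_enrichment <- function(fluor_channel, contact, opposite, background = 0) {
  stopifnot(is.matrix(fluor_channel))
  m_c <- roi_mask(contact, dim(fluor_channel))
  m_o <- roi_mask(opposite, dim(fluor_channel))
  if (!any(m_c) || !any(m_o)) abort("Contact and opposite ROIs must be non-empty.")
  n_c <- sum(m_c); n_o <- sum(m_o)
  if (abs(n_c - n_o) > 0.1 * max(n_c, n_o)) {
    warn(sprintf("Contact (%d px) and opposite (%d px) ROI sizes differ by more than 10%%.",
                 n_c, n_o))
  }
  mean_c <- mean(fluor_channel[m_c]) - background
  mean_o <- mean(fluor_channel[m_o]) - background
  if (mean_o <= 0) {
    abort("Opposite-side mean intensity is at or below background; ratio undefined.")
  }
  tibble(ratio = mean_c / mean_o, mean_contact = mean_c, mean_opposite = mean_o,
         n_contact = n_c, n_opposite = n_o)
}
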