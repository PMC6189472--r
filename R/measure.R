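#' Per-frame intensity trace over an ROI
#'
#' Applies a summary statistic to the pixels of a rasterized ROI in every
#' frame of one channel. `integrated_density` is the plain sum of pixel
#' intensities over the ROI, the quantity used for relative-intensity time
#' courses; `mean` is the average used by FRAP and enrichment measurements.
#'
#' @param stack An [image_stack()].
#' @param roi A rasterizable [roi].
#' @param channel Channel label or index.
#' @param statistic `"mean"` or `"integrated_density"`.
#' @return A tibble with columns `frame`, `t` (seconds, 0 at the first frame)
#'   and `value`, plus `roi`/`channel`/`statistic` metadata columns.
#' @export
roi_trace <- function(stack, roi, channel = 1L,
                      statistic = c("mean", "integrated_density")) {
  statistic <- match.arg(statistic)
  ch <- resolve_channel(stack, channel)
  mask <- roi_mask(roi, dim(stack$data)[3:4])
  if (!any(mask)) abort("ROI mask is empty; cannot extract a trace.")
  fun <- if (statistic == "mean") mean else sum
  vals <- vapply(seq_len(n_frames(stack)), function(f) {
    fun(stack$data[f, ch, , ][mask])
  }, numeric(1))
  tibble(
    frame = seq_len(n_frames(stack)),
    t = frame_times(stack),
    value = vals,
    roi = roi$label,
    channel = stack$channel_names[ch],
    statistic = statistic
  )
}

#' Estimate per-frame background
#'
#' With a background ROI: the per-frame mean intensity inside it. Without: a
#' darkest-peak heuristic, the mode of a 256-bin intensity histogram per
#' frame — appropriate when most of the field is background (sparse cells).
#' An explicit ROI always overrides the heuristic.
#'
#' @param stack An [image_stack()].
#' @param channel Channel label or index.
#' @param background_roi Optional [roi] over a signal-free region.
#' @param nbins Histogram bins for the mode heuristic.
#' @return Numeric vector, one background level per frame.
#' @export
estimate_background <- function(stack, channel = 1L, background_roi = NULL,
                                nbins = 256L) {
  ch <- resolve_channel(stack, channel)
  if (!is.null(background_roi)) {
    mask <- roi_mask(background_roi, dim(stack$data)[3:4])
    if (!any(mask)) abort("Background ROI mask is empty.")
    return(vapply(seq_len(n_frames(stack)), function(f) {
      mean(stack$data[f, ch, , ][mask])
    }, numeric(1)))
  }
  vapply(seq_len(n_frames(stack)), function(f) {
    x <- as.vector(stack$data[f, ch, , ])
    rng <- range(x)
    if (diff(rng) == 0) return(rng[1])
    h <- graphics::hist(x, breaks = seq(rng[1], rng[2], length.out = nbins + 1L),
                        plot = FALSE)
    h$mids[which.max(h$counts)]
  }, numeric(1))
}
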