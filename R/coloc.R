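# Co-localization: thresholding, intensity-weighted Mander's M1/M2,
# Pearson correlation, and per-frame time series.

#' Threshold a channel for microcluster selection
#'
#' Concretizes "appropriate thresholding which only includes the
#' microclusters": Otsu (default), a percentile of the intensity
#' distribution, or a fixed value. The threshold actually used is always
#' returned so analyses are reproducible.
#'
#' @param image 2-D numeric matrix.
#' @param method `"otsu"`, `"percentile"` or `"fixed"`.
#' @param p Percentile (0-100) for `method = "percentile"`; the mask keeps
#'   the brightest `100 - p` percent of pixels.
#' @param value Threshold for `method = "fixed"`; mask is `image >= value`.
#' @return A list with `mask` (logical matrix) and `threshold`.
#' @export
threshold_channel <- function(image, method = c("otsu", "percentile", "fixed"),
                              p = 99, value = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(image))
  thr <- switch(method,
    otsu = otsu_threshold(image),
    percentile = {
      n <- length(image)
      k <- max(1L, round(n * (1 - p / 100)))
      sort(as.vector(image), decreasing = TRUE)[k]
    },
    fixed = {
      if (is.null(value)) abort("`value` is required for a fixed threshold.")
      value
    })
  list(mask = image >= thr, threshold = thr)
}

#' Intensity-weighted Mander's coefficients
#'
#' JACoP-convention Mander's coefficients over an optional ROI:
#' `M1 = sum(A over maskA & maskB) / sum(A over maskA)` — the fraction of
#' above-threshold channel-A intensity lying where channel B is above its
#' threshold — and `M2` with the roles of the channels swapped. Swapping the
#' channels (with their masks) swaps M1 and M2 exactly. A zero denominator
#' yields `NA` with a flag rather than an error.
#'
#' @param chA,chB 2-D numeric matrices (the two channels).
#' @param maskA,maskB Logical threshold masks for the two channels.
#' @param roi Optional rasterizable [roi] restricting the computation.
#' @return A one-row tibble: `m1`, `m2`, `flag`.
#' @export
manders <- function(chA, chB, maskA, maskB, roi = NULL) {
  stopifnot(all(dim(chA) == dim(chB)), all(dim(chA) == dim(maskA)),
            all(dim(chA) == dim(maskB)))
  sel <- if (is.null(roi)) {
    matrix(TRUE, nrow(chA), ncol(chA))
  } else {
    roi_mask(roi, dim(chA))
  }
  a_in <- maskA & sel
  b_in <- maskB & sel
  denom1 <- sum(chA[a_in])
  denom2 <- sum(chB[b_in])
  flag <- NA_character_
  m1 <- if (denom1 > 0) sum(chA[a_in & b_in]) / denom1 else NA_real_
  m2 <- if (denom2 > 0) sum(chB[a_in & b_in]) / denom2 else NA_real_
  if (denom1 <= 0 || denom2 <= 0) flag <- "zero_denominator"
  tibble(m1 = m1, m2 = m2, flag = flag)
}

#' Pearson correlation between two channels
#'
#' Product-moment correlation of pixel intensities over an optional ROI.
#' Zero variance in either channel yields `NA` with a warning.
#'
#' @inheritParams manders
#' @return Correlation coefficient in `[-1, 1]`, or `NA`.
#' @export
coloc_pearson <- function(chA, chB, roi = NULL) {
  stopifnot(all(dim(chA) == dim(chB)))
  sel <- if (is.null(roi)) rep(TRUE, length(chA)) else as.vector(roi_mask(roi, dim(chA)))
  a <- as.vector(chA)[sel]; b <- as.vector(chB)[sel]
  if (length(a) < 2) abort("Need at least 2 pixels for a correlation.")
  if (sd(a) == 0 || sd(b) == 0) {
    warn("Zero variance in a channel; Pearson coefficient undefined.")
    return(NA_real_)
  }
  cor(a, b)
}

#' Co-localization time series over a fixed ROI
#'
#' Applies the same ROI to every frame and recomputes both channel
#' thresholds per frame (the method stays fixed; the values are recorded),
#' then evaluates Mander's M1/M2 and the Pearson coefficient. Per-frame
#' failures (e.g. a blank frame) propagate as `NA` rows without aborting the
#' series.
#'
#' @param stack An [image_stack()] with both channels.
#' @param chA,chB Channel labels or indices.
#' @param roi Optional rasterizable [roi] (e.g. the central part of the
#'   cell-bilayer interface).
#' @param method,p,value Thresholding controls, see [threshold_channel()].
#' @return A tibble with one row per frame: `frame`, `t`, `m1`, `m2`,
#'   `pearson`, `threshold_a`, `threshold_b`, `flag`.
#' @export
coloc_timeseries <- function(stack, chA = 1L, chB = 2L, roi = NULL,
                             method = c("otsu", "percentile", "fixed"),
                             p = 99, value = NULL) {
  method <- match.arg(method)
  ia <- resolve_channel(stack, chA)
  ib <- resolve_channel(stack, chB)
  ts <- frame_times(stack)
  rows <- lapply(seq_len(n_frames(stack)), function(f) {
    A <- stack$data[f, ia, , ]
    B <- stack$data[f, ib, , ]
    res <- tryCatch({
      ta <- threshold_channel(A, method, p = p, value = value)
      tb <- threshold_channel(B, method, p = p, value = value)
      m <- manders(A, B, ta$mask, tb$mask, roi = roi)
      r <- suppressWarnings(coloc_pearson(A, B, roi = roi))
      tibble(frame = f, t = ts[f], m1 = m$m1, m2 = m$m2, pearson = r,
             threshold_a = ta$threshold, threshold_b = tb$threshold,
             flag = m$flag)
    }, error = function(e) {
      tibble(frame = f, t = ts[f], m1 = NA_real_, m2 = NA_real_,
             pearson = NA_real_, threshold_a = NA_real_, threshold_b = NA_real_,
             flag = conditionMessage(e))
    })
    res
  })
  bind_rows(rows)
}

#' Relative integrated-density time course
#'
#' Per-frame integrated density (sum of intensities) over an ROI, divided by
#' the integrated density at the frame nearest a reference time — the
#' convention used for receptor-accumulation curves with the reference at
#' the start of synapse formation (t = 2 min in the source workflow).
#'
#' @param stack An [image_stack()].
#' @param channel Channel label or index.
#' @param roi A rasterizable [roi].
#' @param t_ref Reference time in seconds (snapped to the nearest frame;
#'   must lie within the stack duration).
#' @return A tibble: `frame`, `t`, `integrated_density`, `relative`.
#' @export
relative_intensity_timeseries <- function(stack, channel, roi, t_ref) {
  ts <- frame_times(stack)
  if (t_ref < min(ts) || t_ref > max(ts)) {
    abort("`t_ref` lies outside the stack duration.")
  }
  tr <- roi_trace(stack, roi, channel, statistic = "integrated_density")
  ref_frame <- which.min(abs(ts - t_ref))
  ref <- tr$value[ref_frame]
  if (ref == 0) abort("Integrated density at the reference frame is 0.")
  tibble(frame = tr$frame, t = tr$t,
         integrated_density = tr$value, relative = tr$value / ref)
}
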