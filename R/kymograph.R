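# Kymograph extraction along a line ROI and streak-slope speed estimation.

#' Extract a kymograph along a line
#'
#' Samples one channel along a line ROI at 1-pixel steps by bilinear
#' interpolation, for every frame in a time range — the equivalent of a
#' dynamic-reslice operation. Rows are frames (time increases downward),
#' columns are positions from the first endpoint; a `transpose` flag is
#' available for display conventions in which static objects appear as
#' horizontal lines.
#'
#' @param stack An [image_stack()].
#' @param channel Channel label or index.
#' @param line A line [roi] (endpoints inside the image).
#' @param t_range Optional `c(t0, t1)` in seconds restricting the frames.
#' @param transpose Return the transposed (position x time) image instead.
#' @return A `kymograph` object: `image` (time x position matrix), `dt` (s),
#'   `ds` (um per position sample), `t0` (time of the first row), `line`.
#' @export
extract_kymograph <- function(stack, channel, line, t_range = NULL,
                              transpose = FALSE) {
  stopifnot(inherits(line, "roi"))
  if (line$kind != "line") abort("`line` must be a line ROI.")
  ch <- resolve_channel(stack, channel)
  d <- dim(stack$data)[3:4]
  for (pt in list(c(line$x1, line$y1), c(line$x2, line$y2))) {
    if (pt[1] < 0 || pt[1] > d[2] - 1 || pt[2] < 0 || pt[2] > d[1] - 1) {
      abort("Line endpoints must lie inside the image.")
    }
  }
  len <- sqrt((line$x2 - line$x1)^2 + (line$y2 - line$y1)^2)
  if (len < 1) abort("Degenerate line: endpoints are less than one pixel apart.")
  n_pos <- floor(len) + 1L
  s <- seq(0, len, length.out = n_pos) / len
  xs <- line$x1 + s * (line$x2 - line$x1)
  ys <- line$y1 + s * (line$y2 - line$y1)

  ts <- frame_times(stack)
  frames <- seq_len(n_frames(stack))
  if (!is.null(t_range)) {
    frames <- frames[ts >= t_range[1] & ts <= t_range[2]]
    if (!length(frames)) abort("`t_range` selects no frames.")
  }
  img <- matrix(0, length(frames), n_pos)
  for (i in seq_along(frames)) {
    img[i, ] <- bilinear_sample(stack$data[frames[i], ch, , ], xs, ys)
  }
  ds <- (len / (n_pos - 1L)) * stack$pixel_size_um
  structure(list(
    image = if (transpose) t(img) else img,
    transposed = transpose,
    dt = stack$frame_interval_s,
    ds = ds,
    t0 = ts[frames[1]],
    line = line
  ), class = "kymograph")
}

# Bilinear interpolation of matrix `m` at continuous (x = col, y = row)
# pixel-center coordinates, clamped at the borders.
bilinear_sample <- function(m, xs, ys) {
  nr <- nrow(m); nc <- ncol(m)
  x0 <- pmin(pmax(floor(xs), 0), nc - 1L)
  y0 <- pmin(pmax(floor(ys), 0), nr - 1L)
  x1 <- pmin(x0 + 1L, nc - 1L)
  y1 <- pmin(y0 + 1L, nr - 1L)
  fx <- xs - x0; fy <- ys - y0
  idx <- function(r, c) m[cbind(r + 1L, c + 1L)]
  (1 - fx) * (1 - fy) * idx(y0, x0) + fx * (1 - fy) * idx(y0, x1) +
    (1 - fx) * fy * idx(y1, x0) + fx * fy * idx(y1, x1)
}

#' @export
print.kymograph <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<kymograph> %d frames x %d positions (dt = %.3g s, ds = %.4g um)%s\n",
              if (x$transposed) d[2] else d[1],
              if (x$transposed) d[1] else d[2],
              x$dt, x$ds, if (x$transposed) " [transposed]" else ""))
  invisible(x)
}

#' Estimate microcluster speed from a kymograph streak
#'
#' Locates, in each kymograph row, the intensity-weighted centre of the
#' above-threshold signal, then fits a robust line to position versus time.
#' The absolute slope is the transport speed. The estimator assumes one
#' dominant streak; rows in which the above-threshold signal splits into
#' several separated runs trigger a warning.
#'
#' @param kymo A [extract_kymograph()] result.
#' @param threshold Intensity threshold; defaults to Otsu over the whole
#'   kymograph, with half the maximum as fallback.
#' @return A one-row tibble: `speed_um_s`, `se_um_s` (standard error of the
#'   slope), `n_rows` (rows with signal), `intercept_um`.
#' @export
estimate_cluster_speed <- function(kymo, threshold = NULL) {
  stopifnot(inherits(kymo, "kymograph"))
  img <- if (kymo$transposed) t(kymo$image) else kymo$image
  if (kymo$dt <= 0) abort("Kymograph has no time axis (dt = 0).")
  if (max(img) <= min(img)) abort("No above-threshold signal in the kymograph.")
  thr <- threshold %||% tryCatch(otsu_threshold(img),
                                 error = function(e) max(img) / 2)
  above <- img >= thr & img > 0
  if (!any(above)) abort("No above-threshold signal in the kymograph.")
  n_runs <- apply(above, 1L, function(r) {
    sum(diff(c(FALSE, r)) == 1L)
  })
  rows <- which(rowSums(above) > 0)
  if (median(n_runs[rows]) > 1) {
    warn("Multiple streaks per row detected; the single-streak assumption is violated.")
  }
  pos <- vapply(rows, function(i) {
    wts <- img[i, ] * above[i, ]
    sum(wts * (seq_len(ncol(img)) - 1)) / sum(wts)
  }, numeric(1))
  t_s <- (rows - 1) * kymo$dt
  pos_um <- pos * kymo$ds
  if (length(rows) < 3) abort("Too few rows with signal to fit a speed.")
  fit <- tryCatch(MASS::rlm(pos_um ~ t_s, maxit = 100),
                  error = function(e) lm(pos_um ~ t_s))
  sm <- summary(fit)$coefficients  # rlm names columns Value/Std. Error
  tibble(speed_um_s = abs(sm[2, 1]),
         se_um_s = sm[2, 2],
         n_rows = length(rows),
         intercept_um = sm[1, 1])
}
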