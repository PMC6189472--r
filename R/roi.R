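#' Regions of interest
#'
#' ROIs live in continuous, 0-based, pixel-center image coordinates: pixel
#' `(i, j)` (row i, column j, both starting at 0) is centred at `x = j`,
#' `y = i` and spans `[j - 0.5, j + 0.5) x [i - 0.5, i + 0.5)`. A pixel
#' belongs to a rasterized ROI iff its centre lies inside the ROI. This
#' convention is fixed so ROI JSON sidecars are portable across tools.
#'
#' @param cx,cy Centre coordinates (x = column, y = row), pixels.
#' @param r Circle radius in pixels (> 0).
#' @param label Optional text label.
#' @return A `roi` object.
#' @name roi
NULL

new_roi <- function(kind, params, label) {
  structure(c(list(kind = kind, label = label), params), class = "roi")
}

#' @rdname roi
#' @export
roi_circle <- function(cx, cy, r, label = "circle") {
  if (!is.numeric(r) || r <= 0) abort("Circle radius must be > 0.")
  new_roi("circle", list(cx = cx, cy = cy, r = r), label)
}

#' @rdname roi
#' @param x,y Top-left corner of the rectangle (pixel-center coordinates).
#' @param width,height Rectangle extents in pixels (> 0).
#' @export
roi_rect <- function(x, y, width, height, label = "rect") {
  if (width <= 0 || height <= 0) abort("Rectangle width and height must be > 0.")
  new_roi("rectangle", list(x = x, y = y, width = width, height = height), label)
}

#' @rdname roi
#' @param x1,y1,x2,y2 Line endpoints.
#' @export
roi_line <- function(x1, y1, x2, y2, label = "line") {
  if (x1 == x2 && y1 == y2) abort("Line endpoints must be distinct.")
  new_roi("line", list(x1 = x1, y1 = y1, x2 = x2, y2 = y2), label)
}

#' @rdname roi
#' @param xs,ys Polygon vertex coordinates (>= 3 vertices, simple polygon).
#' @export
roi_polygon <- function(xs, ys, label = "polygon") {
  if (length(xs) != length(ys)) abort("`xs` and `ys` must have equal length.")
  if (length(xs) < 3) abort("A polygon needs at least 3 vertices.")
  new_roi("polygon", list(xs = as.numeric(xs), ys = as.numeric(ys)), label)
}

#' @export
print.roi <- function(x, ...) {
  p <- x[setdiff(names(x), c("kind", "label"))]
  cat(sprintf("<roi:%s> '%s' %s\n", x$kind, x$label,
              paste(names(p), vapply(p, function(v) paste(signif(v, 5), collapse = ","),
                                     character(1)), sep = "=", collapse = " ")))
  invisible(x)
}

#' Rasterize an ROI to a binary mask
#'
#' A pixel is included iff its centre lies inside the ROI (circle: distance
#' `<= r`; rectangle: half-open `[x, x + width) x [y, y + height)`; polygon:
#' point-in-polygon with boundary included). Line ROIs have no area and are
#' rejected; use [extract_kymograph()] for line sampling.
#'
#' @param roi A [roi] object (circle, rectangle or polygon).
#' @param shape Image shape `c(rows, cols)`.
#' @return Logical matrix of dimension `shape`. An ROI lying entirely outside
#'   the image yields an empty mask with a warning.
#' @export
roi_mask <- function(roi, shape) {
  stopifnot(inherits(roi, "roi"), length(shape) == 2, all(shape >= 1))
  g <- pixel_grid(shape)
  m <- switch(roi$kind,
    circle = (g$x - roi$cx)^2 + (g$y - roi$cy)^2 <= roi$r^2,
    rectangle = g$x >= roi$x & g$x < roi$x + roi$width &
                g$y >= roi$y & g$y < roi$y + roi$height,
    polygon = {
      inp <- pracma::inpolygon(as.vector(g$x), as.vector(g$y),
                               roi$xs, roi$ys, boundary = TRUE)
      matrix(inp, nrow = shape[1], ncol = shape[2])
    },
    line = abort("Line ROIs have zero area and cannot be rasterized; use extract_kymograph()."),
    abort(sprintf("Unknown ROI kind '%s'.", roi$kind))
  )
  if (!any(m)) warn(sprintf("ROI '%s' lies entirely outside the image; mask is empty.", roi$label))
  m
}

#' Analytic ROI area in square micrometres
#' @param roi A [roi] object.
#' @param pixel_size_um Pixel size, um/px.
#' @return Area in um^2 (circle/rectangle/polygon; error for lines).
#' @export
roi_area_um2 <- function(roi, pixel_size_um = 1) {
  a_px2 <- switch(roi$kind,
    circle = pi * roi$r^2,
    rectangle = roi$width * roi$height,
    polygon = abs(pracma::polyarea(roi$xs, roi$ys)),
    line = abort("Line ROIs have zero area."))
  a_px2 * pixel_size_um^2
}

#' Read / write ROI JSON sidecars
#'
#' The sidecar is a JSON array of objects
#' `{label, kind, <params...>, units: "pixel"}` in the package's 0-based
#' pixel-center coordinate convention (see [roi]).
#'
#' @param path JSON file path.
#' @return `read_rois()`: a named list of [roi] objects (names are labels).
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  rois <- lapply(raw, function(r) {
    switch(r$kind,
      circle = roi_circle(r$cx, r$cy, r$r, label = r$label %||% "circle"),
      rectangle = roi_rect(r$x, r$y, r$width, r$height, label = r$label %||% "rect"),
      line = roi_line(r$x1, r$y1, r$x2, r$y2, label = r$label %||% "line"),
      polygon = roi_polygon(unlist(r$xs), unlist(r$ys), label = r$label %||% "polygon"),
      abort(sprintf("Unknown ROI kind '%s' in %s.", r$kind, path)))
  })
  setNames(rois, vapply(rois, function(r) r$label, character(1)))
}

#' @rdname read_rois
#' @param rois A list of [roi] objects.
#' @export
write_rois <- function(rois, path) {
  if (inherits(rois, "roi")) rois <- list(rois)
  out <- lapply(rois, function(r) {
    c(list(label = r$label, kind = r$kind),
      r[setdiff(names(r), c("kind", "label"))],
      list(units = "pixel"))
  })
  jsonlite::write_json(unname(out), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
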