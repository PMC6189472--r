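#' Multi-channel time-lapse image stack
#'
#' The package's single in-memory carrier for image data: a 4-D numeric array
#' indexed `(frame, channel, row, col)` together with the physical pixel size
#' (micrometres per pixel) and the frame interval (seconds; 0 for a single
#' frame). All readers permute their input to this axis order at the boundary.
#'
#' @param data Numeric array. 2-D `(row, col)`, 3-D `(frame, row, col)` and
#'   4-D `(frame, channel, row, col)` inputs are accepted; lower-dimensional
#'   inputs are promoted with size-1 frame/channel axes.
#' @param pixel_size_um Physical pixel size in micrometres per pixel (> 0).
#' @param frame_interval_s Frame interval in seconds (>= 0; 0 for one frame).
#' @param channel_names Character vector of channel labels; defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @return An `image_stack` object.
#' @examples
#' st <- image_stack(array(runif(2 * 16 * 16), c(2, 16, 16)),
#'                   pixel_size_um = 0.1, frame_interval_s = 0.5)
#' dim(st$data)
#' @export
image_stack <- function(data, pixel_size_um = 1, frame_interval_s = 0,
                        channel_names = NULL) {
  if (is.matrix(data)) {
    data <- array(data, c(1L, 1L, nrow(data), ncol(data)))
  } else if (length(dim(data)) == 3L) {
    d <- dim(data)
    data <- array(data, c(d[1], 1L, d[2], d[3]))
  } else if (length(dim(data)) != 4L) {
    abort("`data` must be a 2-D, 3-D (frame, row, col) or 4-D (frame, channel, row, col) array.")
  }
  if (!all(is.finite(data))) abort("All intensities must be finite.")
  if (any(data < 0)) abort("All intensities must be >= 0.")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a positive number.")
  }
  if (!is.numeric(frame_interval_s) || frame_interval_s < 0) {
    abort("`frame_interval_s` must be >= 0.")
  }
  n_ch <- dim(data)[2]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(n_ch))
  if (length(channel_names) != n_ch) {
    abort(sprintf("`channel_names` has length %d but the stack has %d channels.",
                  length(channel_names), n_ch))
  }
  structure(
    list(data = data, pixel_size_um = pixel_size_um,
         frame_interval_s = frame_interval_s,
         channel_names = as.character(channel_names)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_stack> %d frame(s) x %d channel(s) x %d x %d px\n  pixel size %.4g um/px, frame interval %.4g s\n  channels: %s\n",
    d[1], d[2], d[3], d[4], x$pixel_size_um, x$frame_interval_s,
    paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' Number of frames / channels of a stack
#' @param stack An [image_stack()].
#' @return Integer count.
#' @export
n_frames <- function(stack) dim(stack$data)[1]

#' @rdname n_frames
#' @export
n_channels <- function(stack) dim(stack$data)[2]

#' Frame times of a stack
#'
#' Times in seconds with t = 0 at the first frame.
#' @param stack An [image_stack()].
#' @return Numeric vector, one entry per frame.
#' @export
frame_times <- function(stack) (seq_len(n_frames(stack)) - 1) * stack$frame_interval_s

# Resolve a channel given by label or 1-based index to an index.
resolve_channel <- function(stack, channel) {
  if (is.numeric(channel)) {
    ch <- as.integer(channel)
    if (ch < 1L || ch > n_channels(stack)) {
      abort(sprintf("Channel index %d out of range (stack has %d channels).",
                    ch, n_channels(stack)))
    }
    return(ch)
  }
  ch <- match(channel, stack$channel_names)
  if (is.na(ch)) {
    abort(sprintf("Channel '%s' not found; available: %s.",
                  channel, paste(stack$channel_names, collapse = ", ")))
  }
  ch
}

#' Extract one frame of one channel as a matrix
#' @param stack An [image_stack()].
#' @param frame 1-based frame index.
#' @param channel Channel label or 1-based index.
#' @return A `(row, col)` numeric matrix.
#' @export
get_frame <- function(stack, frame = 1L, channel = 1L) {
  ch <- resolve_channel(stack, channel)
  if (frame < 1L || frame > n_frames(stack)) abort("Frame index out of range.")
  stack$data[frame, ch, , , drop = TRUE]
}

# ---------------------------------------------------------------------------
# TIFF I/O.
#
# Reading goes through tiff::readTIFF (baseline multi-page TIFF, uint8/16 and
# float32 sample formats, ImageDescription honored). Writing is done by a
# minimal baseline TIFF emitter in this file because the installed writer
# clamps values to [0, 1] and cannot store an ImageDescription tag; the
# emitter stores uint16 for integer data within range and float32 otherwise,
# plus a JSON ImageDescription carrying axes and physical metadata.
# ---------------------------------------------------------------------------

#' Read a multi-page TIFF as an image stack
#'
#' Pages are interpreted as `frame x channel` in frame-major order (all
#' channels of frame 1, then frame 2, ...). Files written by [write_stack()]
#' carry a JSON ImageDescription with the axis layout, channel names and
#' physical metadata, which is honored on reading; for foreign files the page
#' count together with `n_channels` determines the layout (default: one
#' channel, pages are frames). Explicit `pixel_size_um` / `frame_interval_s`
#' arguments override embedded metadata.
#'
#' @param path Path to a readable TIFF file.
#' @param pixel_size_um,frame_interval_s Optional physical metadata overrides.
#' @param n_channels Number of channels for files without embedded layout
#'   metadata. Must divide the page count.
#' @param channel_names Optional channel labels override.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size_um = NULL, frame_interval_s = NULL,
                       n_channels = NULL, channel_names = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  # Integer-format pages come back scaled to [0, 1]; undo that. Float pages
  # (sample.format == "float") already carry physical values.
  pages <- lapply(pages, function(p) {
    fmt <- attr(p, "sample.format") %||% "uint"
    if (!identical(fmt, "float")) {
      bits <- attr(p, "bits.per.sample") %||% 16L
      p <- round(p * (2^bits - 1))
    }
    p
  })
  meta <- NULL
  desc <- attr(pages[[1]], "description")
  if (!is.null(desc)) {
    meta <- tryCatch(jsonlite::fromJSON(desc), error = function(e) NULL)
    if (!is.list(meta) || is.null(meta$axes)) meta <- NULL
  }
  # RGB/multi-sample pages: samples become channels.
  if (length(dim(pages[[1]])) == 3L) {
    n_smp <- dim(pages[[1]])[3]
    pages <- unlist(lapply(pages, function(p) {
      lapply(seq_len(n_smp), function(s) p[, , s])
    }), recursive = FALSE)
    if (is.null(n_channels)) n_channels <- n_smp
  }
  n_pages <- length(pages)
  if (!is.null(meta)) {
    nc <- as.integer(meta$n_channels)
    nf <- as.integer(meta$n_frames)
    if (nf * nc != n_pages) {
      abort(sprintf(
        "Ambiguous axis layout: metadata declares %d frames x %d channels but the file has %d pages.",
        nf, nc, n_pages))
    }
  } else {
    nc <- as.integer(n_channels %||% 1L)
    if (n_pages %% nc != 0L) {
      abort(sprintf(
        "Ambiguous axis layout: %d pages are not divisible by %d channels; pass `n_channels` matching the file.",
        n_pages, nc))
    }
    nf <- n_pages %/% nc
  }
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  arr <- array(0, c(nf, nc, h, w))
  for (f in seq_len(nf)) {
    for (c in seq_len(nc)) {
      arr[f, c, , ] <- pages[[(f - 1L) * nc + c]]
    }
  }
  px <- pixel_size_um %||% (if (!is.null(meta)) meta$pixel_size_um else NULL) %||% 1
  dt <- frame_interval_s %||% (if (!is.null(meta)) meta$frame_interval_s else NULL) %||% 0
  chn <- channel_names %||% (if (!is.null(meta)) meta$channel_names else NULL)
  image_stack(arr, pixel_size_um = px, frame_interval_s = dt, channel_names = chn)
}

#' Write an image stack to a multi-page TIFF
#'
#' Pages are written frame-major (all channels of frame 1, then frame 2, ...).
#' Integer-valued data within `[0, 65535]` are stored as uint16, anything else
#' as 32-bit float; metadata (axes, channel names, pixel size, frame interval)
#' goes into a JSON ImageDescription tag so [read_stack()] recovers the stack
#' exactly. The round trip is lossless for integer data and for values exactly
#' representable in float32; other doubles are rounded to float32 precision.
#'
#' @param stack An [image_stack()].
#' @param path Output path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  if (!dir.exists(dirname(path))) {
    abort(sprintf("Parent directory does not exist: %s", dirname(path)))
  }
  d <- dim(stack$data)
  meta <- jsonlite::toJSON(list(
    axes = "TCYX", n_frames = d[1], n_channels = d[2],
    pixel_size_um = stack$pixel_size_um,
    frame_interval_s = stack$frame_interval_s,
    channel_names = stack$channel_names
  ), auto_unbox = TRUE, digits = NA)
  pages <- vector("list", d[1] * d[2])
  for (f in seq_len(d[1])) {
    for (c in seq_len(d[2])) {
      pages[[(f - 1L) * d[2] + c]] <- stack$data[f, c, , , drop = TRUE]
    }
  }
  vals <- unlist(pages, use.names = FALSE)
  as_uint16 <- all(vals == round(vals)) && all(vals >= 0) && all(vals <= 65535)
  write_tiff_pages(pages, path, sample_format = if (as_uint16) "uint16" else "float32",
                   description = as.character(meta))
  invisible(path)
}

# Minimal little-endian baseline TIFF emitter: one strip per page, no
# compression, ImageDescription on the first page.
write_tiff_pages <- function(pages, path, sample_format = c("float32", "uint16"),
                             description = NULL) {
  sample_format <- match.arg(sample_format)
  bps <- if (sample_format == "uint16") 16L else 32L
  smp_fmt <- if (sample_format == "uint16") 1L else 3L
  bytes_per <- bps %/% 8L
  n <- length(pages)
  desc_raw <- NULL
  desc_count <- 0L
  if (!is.null(description)) {
    desc_raw <- c(charToRaw(description), as.raw(0L))
    desc_count <- length(desc_raw)  # ASCII count includes the single NUL
    if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))
  }

  page_bytes <- function(p) nrow(p) * ncol(p) * bytes_per
  n_tags <- function(i) 9L + if (i == 1L && !is.null(desc_raw)) 1L else 0L
  ifd_size <- function(i) 2L + 12L * n_tags(i) + 4L

  # Layout: header | page1 data | desc | IFD1 | page2 data | IFD2 | ...
  offset <- 8L
  data_off <- integer(n); ifd_off <- integer(n)
  for (i in seq_len(n)) {
    data_off[i] <- offset
    offset <- offset + page_bytes(pages[[i]])
    if (i == 1L && !is.null(desc_raw)) {
      desc_off <- offset
      offset <- offset + length(desc_raw)
    }
    ifd_off[i] <- offset
    offset <- offset + ifd_size(i)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  # TIFF tag entry: id, type, count, value/offset. Type 3=SHORT, 4=LONG, 2=ASCII.
  tag_short <- function(id, value) { wr2(id); wr2(3L); wr4(1L); wr2(value); wr2(0L) }
  tag_long <- function(id, value) { wr2(id); wr2(4L); wr4(1L); wr4(value) }

  writeBin(charToRaw("II"), con); wr2(42L); wr4(ifd_off[1])
  for (i in seq_len(n)) {
    p <- pages[[i]]
    v <- as.numeric(t(p))  # row-major strip order
    if (sample_format == "uint16") {
      iv <- as.integer(round(v))
      iv <- ifelse(iv > 32767L, iv - 65536L, iv)  # two's-complement low bytes
      writeBin(iv, con, size = 2L, endian = "little")
    } else {
      writeBin(v, con, size = 4L, endian = "little")
    }
    if (i == 1L && !is.null(desc_raw)) writeBin(desc_raw, con)
    wr2(n_tags(i))
    tag_long(256L, ncol(p))             # ImageWidth
    tag_long(257L, nrow(p))             # ImageLength
    tag_short(258L, bps)                # BitsPerSample
    tag_short(259L, 1L)                 # Compression: none
    tag_short(262L, 1L)                 # Photometric: BlackIsZero
    if (i == 1L && !is.null(desc_raw)) {
      wr2(270L); wr2(2L); wr4(desc_count); wr4(desc_off)
    }
    tag_long(273L, data_off[i])         # StripOffsets
    tag_short(278L, nrow(p))            # RowsPerStrip
    tag_long(279L, page_bytes(p))       # StripByteCounts
    tag_short(339L, smp_fmt)            # SampleFormat
    wr4(if (i < n) ifd_off[i + 1L] else 0L)
  }
  invisible(path)
}
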