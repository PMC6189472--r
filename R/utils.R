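# Internal helpers shared across modules.

# Wilson score interval for a binomial proportion.
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

# Otsu threshold on an arbitrary-range image; returns the threshold on the
# original intensity scale. Errors on (near-)constant input.
otsu_threshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) {
    abort("Otsu threshold undefined for a constant image; use a fixed threshold.",
          class = "isquant_constant_image")
  }
  x01 <- (x - rng[1]) / diff(rng)
  thr01 <- EBImage::otsu(EBImage::Image(matrix(x01, nrow = 1L)),
                         range = c(0, 1), levels = levels)
  rng[1] + thr01 * diff(rng)
}

# Gaussian blob rendered on an image grid (0-based pixel-center coords).
# Returns a matrix of the same shape as `dim`.
render_blob <- function(dim, cx, cy, sigma, amplitude = 1) {
  rows <- matrix(seq_len(dim[1]) - 1, nrow = dim[1], ncol = dim[2])
  cols <- matrix(seq_len(dim[2]) - 1, nrow = dim[1], ncol = dim[2], byrow = TRUE)
  amplitude * exp(-((cols - cx)^2 + (rows - cy)^2) / (2 * sigma^2))
}

# Coordinate grids (0-based pixel centers) for a (rows, cols) shape.
pixel_grid <- function(shape) {
  list(
    y = matrix(seq_len(shape[1]) - 1, nrow = shape[1], ncol = shape[2]),
    x = matrix(seq_len(shape[2]) - 1, nrow = shape[1], ncol = shape[2], byrow = TRUE)
  )
}

# Apply a noise model (list(model=, ...)) to an image/array, in place on value.
apply_noise <- function(x, noise) {
  if (is.null(noise) || identical(noise$model, "none")) return(x)
  if (identical(noise$model, "gaussian")) {
    return(x + rnorm(length(x), sd = noise$sd))
  }
  if (identical(noise$model, "poisson")) {
    gain <- noise$gain %||% 1
    out <- rpois(length(x), lambda = pmax(x / gain, 0)) * gain
    dim(out) <- dim(x)
    return(out)
  }
  abort(sprintf("Unknown noise model '%s'.", noise$model))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed derivation, kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483647L
}
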