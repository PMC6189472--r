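#' Ground-truth specification of a synthetic scene
#'
#' All synthetic-microscopy generators take a `scene_spec`: a bundle of a
#' mandatory random seed, image geometry, a noise model and per-scene ground
#' truth. Identical specs (including the seed) produce identical output, so
#' every generated fixture is reproducible by construction.
#'
#' Per-kind ground-truth fields:
#'
#' * `"frap"` — `D` (um^2/s), `f_imm` (immobile fraction, 0..1),
#'   `bleach_depth` (0..1), `roi` (bleach [roi]), `model`
#'   (`"exponential"` or `"ellenberg"`), `tau` (s, exponential),
#'   `w` (um, strip width, ellenberg), `acquisition_bleach_rate`
#'   (1/s, optional imaging-induced bleaching of the whole field).
#' * `"spots"` — `spot_diameter_um`, `pitch_um` (grid pitch, must exceed the
#'   diameter), `ratio` (on-spot : off-spot fluorescence, > 0),
#'   `cell_radius_um`, `n_cells`.
#' * `"bead"` — `ratio` (contact : opposite membrane fluorescence, > 0),
#'   `cell_radius_um`, `contact_halfangle_deg`.
#' * `"synapse"` — `n_clusters`, `cluster_radius_um`, `speed_um_s`
#'   (centripetal transport speed, >= 0; 0 is the actin-inhibited regime),
#'   `colocalized_fraction` (0..1), `cell_radius_um`.
#'
#' @param kind One of `"frap"`, `"spots"`, `"bead"`, `"synapse"`.
#' @param seed Integer random seed (mandatory).
#' @param shape Image shape `c(rows, cols)` in pixels.
#' @param pixel_size_um Pixel size, um/px.
#' @param noise Noise model: `noise_none()`, `noise_gaussian(sd)` or
#'   `noise_poisson(gain)`. The default is Gaussian with sd = 2% of the
#'   prebleach/base intensity scale.
#' @param ... Per-kind ground-truth fields, see Details.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(kind = c("frap", "spots", "bead", "synapse"),
                       seed, shape = c(64L, 64L), pixel_size_um = 0.1,
                       noise = noise_gaussian(0.02), ...) {
  kind <- match.arg(kind)
  if (missing(seed)) abort("A `seed` is mandatory in a scene_spec.")
  extra <- list(...)
  defaults <- switch(kind,
    frap = list(D = 0.25, f_imm = 0, bleach_depth = 0.5, model = "exponential",
                tau = 2, w = 1, roi = NULL, acquisition_bleach_rate = 0,
                background_level = 0),
    spots = list(spot_diameter_um = 5, pitch_um = 10, ratio = 2,
                 cell_radius_um = 4, n_cells = 3L),
    bead = list(ratio = 3, cell_radius_um = 3, contact_halfangle_deg = 35),
    synapse = list(n_clusters = 8L, cluster_radius_um = 0.3, speed_um_s = 0.05,
                   colocalized_fraction = 1, cell_radius_um = 5)
  )
  unknown <- setdiff(names(extra), names(defaults))
  if (length(unknown)) {
    abort(sprintf("Unknown scene_spec field(s) for kind '%s': %s",
                  kind, paste(unknown, collapse = ", ")))
  }
  fields <- utils::modifyList(defaults, extra)
  spec <- c(list(kind = kind, seed = as.integer(seed), shape = as.integer(shape),
                 pixel_size_um = pixel_size_um, noise = noise), fields)
  for (fr in intersect(c("f_imm", "bleach_depth", "colocalized_fraction"), names(spec))) {
    v <- spec[[fr]]
    if (!is.null(v) && (v < 0 || v > 1)) abort(sprintf("`%s` must lie in [0, 1].", fr))
  }
  if (!is.null(spec$ratio) && spec$ratio <= 0) abort("`ratio` must be > 0.")
  structure(spec, class = "scene_spec")
}

#' Noise models for synthetic scenes
#' @param sd Gaussian standard deviation, in units of the scene's base
#'   intensity scale (the prebleach plateau is 1 for FRAP curves).
#' @return A noise-model list consumed by the generators.
#' @export
noise_gaussian <- function(sd = 0.02) list(model = "gaussian", sd = sd)

#' @rdname noise_gaussian
#' @export
noise_none <- function() list(model = "none")

#' @rdname noise_gaussian
#' @param gain Photons-per-count gain of the Poisson model.
#' @export
noise_poisson <- function(gain = 1) list(model = "poisson", gain = gain)

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec:%s> seed=%d shape=%dx%d px=%.3g um noise=%s\n",
              x$kind, x$seed, x$shape[1], x$shape[2], x$pixel_size_um,
              x$noise$model))
  invisible(x)
}
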