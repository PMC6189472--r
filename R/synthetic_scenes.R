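# Synthetic micropattern, bead-contact and synapse scenes with known
# ground truth, used as fixtures for segmentation, enrichment,
# co-localization, kymograph and synapse-scoring analyses.

#' Generate a micropatterned antibody-spot scene
#'
#' Emulates cells spread over a regular grid of circular antibody spots
#' surrounded by fibronectin. Three channels are rendered:
#'
#' 1. `spots` — bright disks (intensity 100) on the grid, zero elsewhere;
#' 2. `fluor` — receptor fluorescence over each cell: base intensity 50
#'    off-spot and `ratio * 50` on-spot (so the true on/off enrichment is
#'    exactly `ratio`), zero outside cells;
#' 3. `dic` — a DIC-like rendering: mid-grey with a bright intensity ridge at
#'    each cell edge (sufficient for edge-based segmentation, not
#'    optics-accurate).
#'
#' Cells are disks centred on distinct spots so that both on- and off-spot
#' regions are non-empty.
#'
#' @param spec A `"spots"` [scene_spec()] (`spot_diameter_um`, `pitch_um`,
#'   `ratio`, `cell_radius_um`, `n_cells`).
#' @return A list with `stack` (3-channel [image_stack()]), `masks` (the
#'   ground-truth [mask_set()]: spots, labeled cells, on/off-spot partition)
#'   and `spec`.
#' @export
generate_spot_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"), spec$kind == "spots")
  if (spec$pitch_um <= spec$spot_diameter_um) abort("Grid pitch must exceed the spot diameter.")
  if (2 * spec$cell_radius_um >= spec$pitch_um) {
    abort("Cells would touch: 2 * cell_radius_um must be below the grid pitch.")
  }
  set.seed(spec$seed)
  px <- spec$pixel_size_um
  pitch <- spec$pitch_um / px
  r_spot <- spec$spot_diameter_um / 2 / px
  r_cell <- spec$cell_radius_um / px
  n_cells <- spec$n_cells

  # Image sized to hold n_cells spots along a row-major grid with margin.
  n_col_spots <- min(n_cells, 3L)
  n_row_spots <- ceiling(n_cells / n_col_spots)
  margin <- r_cell + 12
  w <- ceiling(2 * margin + (n_col_spots - 1) * pitch)
  h <- ceiling(2 * margin + (n_row_spots - 1) * pitch)
  shape <- c(h, w)
  if (2 * r_cell >= min(shape)) abort("Cell larger than image; reduce cell_radius_um.")

  centres <- do.call(rbind, lapply(seq_len(n_cells) - 1L, function(i) {
    c(x = margin + (i %% n_col_spots) * pitch,
      y = margin + (i %/% n_col_spots) * pitch)
  }))

  spots_mask <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(centres))) {
    spots_mask <- spots_mask |
      roi_mask(roi_circle(centres[i, 1], centres[i, 2], r_spot, "spot"), shape)
  }
  cells <- matrix(0L, h, w)
  dic <- matrix(100, h, w)
  fluor <- matrix(0, h, w)
  g <- pixel_grid(shape)
  for (i in seq_len(n_cells)) {
    dist <- sqrt((g$x - centres[i, 1])^2 + (g$y - centres[i, 2])^2)
    cell_mask <- dist <= r_cell
    cells[cell_mask] <- i
    fluor[cell_mask] <- 50
    dic[abs(dist - r_cell) <= 1] <- 180  # edge ridge
  }
  fluor[cells > 0 & spots_mask] <- 50 * spec$ratio
  spotch <- ifelse(spots_mask, 100, 0)

  arr <- array(0, c(1L, 3L, h, w))
  arr[1, 1, , ] <- apply_noise(spotch, spec$noise)
  arr[1, 2, , ] <- apply_noise(fluor, spec$noise)
  arr[1, 3, , ] <- apply_noise(dic, spec$noise)
  arr[arr < 0] <- 0
  stack <- image_stack(arr, pixel_size_um = px,
                       channel_names = c("spots", "fluor", "dic"))
  masks <- mask_set(spots = spots_mask, cells = cells)
  list(stack = stack, masks = masks, spec = spec)
}

#' Generate a cell-bead contact scene
#'
#' A membrane ring (annulus) of a cell in a mid-plane confocal section, with
#' the bead-contact arc at intensity `ratio` times the opposite arc. The
#' scene is mirror-symmetric about the vertical image axis, and the returned
#' contact and opposite rectangle ROIs are exact mirror images, so their
#' pixel counts are equal by construction.
#'
#' @param spec A `"bead"` [scene_spec()] (`ratio`, `cell_radius_um`,
#'   `contact_halfangle_deg`).
#' @return A list with `stack` (single-channel [image_stack()]), `contact`
#'   and `opposite` (equal-area [roi] rectangles over the two membrane arcs)
#'   and `spec`.
#' @export
generate_bead_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"), spec$kind == "bead")
  set.seed(spec$seed)
  px <- spec$pixel_size_um
  R <- spec$cell_radius_um / px
  half_w <- 2  # membrane half-thickness, px
  shape <- spec$shape
  cx <- (shape[2] - 1) / 2  # exact mirror axis of the pixel grid
  cy <- (shape[1] - 1) / 2
  if (R + half_w + 2 > min(cx, cy)) abort("Cell ring does not fit the image.")
  g <- pixel_grid(shape)
  dist <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
  ring <- abs(dist - R) <= half_w
  half_ang <- spec$contact_halfangle_deg * pi / 180

  # Mirror-image rectangles over the two membrane arcs (x mirror:
  # j <-> (W-1) - j); their pixel counts are equal by symmetry. The contact
  # arc is defined as the ring portion inside the contact rectangle, so the
  # measured enrichment equals the prescribed ratio exactly on noiseless
  # scenes.
  rw <- 2 * half_w + 4
  rh <- 2 * (R + half_w) * sin(half_ang) + 4
  x0 <- cx + R * cos(half_ang) - half_w - 2
  contact <- roi_rect(x0, cy - rh / 2, rw, rh, label = "contact")
  opposite <- roi_rect(2 * cx - x0 - rw, cy - rh / 2, rw, rh, label = "opposite")

  base <- 50
  img <- matrix(0, shape[1], shape[2])
  img[ring] <- base
  img[ring & roi_mask(contact, shape)] <- base * spec$ratio
  img <- apply_noise(img, spec$noise)
  img[img < 0] <- 0

  stack <- image_stack(array(img, c(1L, 1L, shape[1], shape[2])),
                       pixel_size_um = px, channel_names = "fluor")
  list(stack = stack, contact = contact, opposite = opposite, spec = spec)
}

#' Generate a two-channel synapse time-lapse
#'
#' Emulates TIRF imaging of microcluster transport during
#' immunological-synapse formation: clusters nucleate on a peripheral ring of
#' the cell footprint and move radially inward at the prescribed speed until
#' they merge into a growing central cluster (cSMAC). With `speed_um_s = 0`
#' the clusters stay put — the actin-inhibited regime. A fraction
#' `colocalized_fraction` of channel-A clusters has a channel-B twin at the
#' same position; the rest of channel B nucleates at interleaved angles so
#' the two channels' clusters are spatially disjoint.
#'
#' @param spec A `"synapse"` [scene_spec()] (`n_clusters`,
#'   `cluster_radius_um`, `speed_um_s`, `colocalized_fraction`,
#'   `cell_radius_um`).
#' @param n_frames Number of frames.
#' @param dt Frame interval, seconds.
#' @return A list with `stack` (2-channel [image_stack()], channels
#'   `"cd6"`/`"cd3"`), `tracks` (tibble: `channel`, `cluster`, `frame`, `t`,
#'   `x`, `y` in pixels, `r_um` radial distance, `merged`) and `spec`.
#' @export
generate_synapse_timelapse <- function(spec, n_frames = 30L, dt = 2) {
  stopifnot(inherits(spec, "scene_spec"), spec$kind == "synapse")
  if (spec$speed_um_s < 0) abort("`speed_um_s` must be >= 0.")
  set.seed(spec$seed)
  px <- spec$pixel_size_um
  shape <- spec$shape
  cx <- (shape[2] - 1) / 2
  cy <- (shape[1] - 1) / 2
  R <- spec$cell_radius_um
  r0 <- 0.85 * R                  # nucleation radius, um
  r_merge <- 0.6                  # merge radius, um
  sigma <- spec$cluster_radius_um / px
  n <- spec$n_clusters
  n_co <- round(spec$colocalized_fraction * n)

  angles_a <- (seq_len(n) - 1) * 2 * pi / max(n, 1L)
  # Non-colocalized B twins sit halfway between A angles (disjoint positions).
  angles_b <- c(angles_a[seq_len(n_co)],
                angles_a[setdiff(seq_len(n), seq_len(n_co))] + pi / max(n, 1L))

  track_rows <- list()
  frames <- array(0, c(n_frames, 2L, shape[1], shape[2]))
  for (f in seq_len(n_frames)) {
    t <- (f - 1) * dt
    rho <- pmax(r0 - spec$speed_um_s * t, r_merge)
    for (chan in 1:2) {
      ang <- if (chan == 1) angles_a else angles_b
      img <- matrix(0, shape[1], shape[2])
      n_merged <- 0L
      for (k in seq_len(n)) {
        merged <- spec$speed_um_s > 0 && rho <= r_merge
        xk <- cx + (rho / px) * cos(ang[k])
        yk <- cy + (rho / px) * sin(ang[k])
        if (merged) { xk <- cx; yk <- cy; n_merged <- n_merged + 1L }
        img <- img + render_blob(shape, xk, yk, sigma, amplitude = 100)
        track_rows[[length(track_rows) + 1L]] <- tibble(
          channel = c("cd6", "cd3")[chan], cluster = k, frame = f, t = t,
          x = xk, y = yk, r_um = sqrt((xk - cx)^2 + (yk - cy)^2) * px,
          merged = merged)
      }
      frames[f, chan, , ] <- apply_noise(img, spec$noise)
    }
  }
  frames[frames < 0] <- 0
  stack <- image_stack(frames, pixel_size_um = px, frame_interval_s = dt,
                       channel_names = c("cd6", "cd3"))
  list(stack = stack, tracks = bind_rows(track_rows), spec = spec)
}

#' Generate a multi-cell synapse-scoring scene
#'
#' A single-frame, four-channel field of cells on a supported lipid bilayer
#' for automated synapse scoring: `cd3` (a compact central cluster for
#' synapse-positive cells, small peripheral clusters for negative ones),
#' `fluor` (uniform receptor fluorescence over each cell), `dil` (uniform
#' bright bilayer tracer) and `bf` (DIC/brightfield-like edge ridges).
#'
#' @param spec A `"synapse"` [scene_spec()]; `cell_radius_um` sets the cell
#'   footprint.
#' @param n_cells Number of cells placed on a grid.
#' @param csmac_present Logical vector (length `n_cells`): which cells carry
#'   a central cSMAC cluster. Negative cells get peripheral clusters instead.
#' @param csmac_radius_um Radius of the central cluster, um.
#' @return A list with `stack` (4-channel [image_stack()]), `cells`
#'   (ground-truth labeled mask), `csmac_present` and `spec`.
#' @export
generate_synapse_condition <- function(spec, n_cells, csmac_present,
                                       csmac_radius_um = 1.4) {
  stopifnot(inherits(spec, "scene_spec"), spec$kind == "synapse",
            length(csmac_present) == n_cells)
  set.seed(spec$seed)
  px <- spec$pixel_size_um
  r_cell <- spec$cell_radius_um / px
  n_col <- ceiling(sqrt(n_cells))
  n_row <- ceiling(n_cells / n_col)
  pitch <- 2 * r_cell + 16
  margin <- r_cell + 12
  w <- ceiling(2 * margin + (n_col - 1) * pitch)
  h <- ceiling(2 * margin + (n_row - 1) * pitch)
  shape <- c(h, w)
  g <- pixel_grid(shape)

  cd3 <- matrix(0, h, w); fluor <- matrix(0, h, w)
  bf <- matrix(100, h, w); cells <- matrix(0L, h, w)
  r_cs <- csmac_radius_um / px
  for (i in seq_len(n_cells)) {
    cxi <- margin + ((i - 1L) %% n_col) * pitch
    cyi <- margin + ((i - 1L) %/% n_col) * pitch
    dist <- sqrt((g$x - cxi)^2 + (g$y - cyi)^2)
    cell_mask <- dist <= r_cell
    cells[cell_mask] <- i
    fluor[cell_mask] <- 60
    bf[abs(dist - r_cell) <= 1] <- 180
    if (isTRUE(csmac_present[i])) {
      cd3[dist <= r_cs] <- 200
    } else {
      # peripheral clusters only: small blobs at 0.8 R, fail the centrality test
      for (ang in (0:3) * pi / 2) {
        bx <- cxi + 0.8 * r_cell * cos(ang)
        by <- cyi + 0.8 * r_cell * sin(ang)
        cd3[(g$x - bx)^2 + (g$y - by)^2 <= (0.25 * r_cs)^2] <- 200
      }
    }
  }
  dil <- matrix(80, h, w)
  arr <- array(0, c(1L, 4L, h, w))
  arr[1, 1, , ] <- apply_noise(cd3, spec$noise)
  arr[1, 2, , ] <- apply_noise(fluor, spec$noise)
  arr[1, 3, , ] <- apply_noise(dil, spec$noise)
  arr[1, 4, , ] <- apply_noise(bf, spec$noise)
  arr[arr < 0] <- 0
  stack <- image_stack(arr, pixel_size_um = px,
                       channel_names = c("cd3", "fluor", "dil", "bf"))
  list(stack = stack, cells = cells, csmac_present = csmac_present, spec = spec)
}
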