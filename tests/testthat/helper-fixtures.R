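# Shared fixture builders (all data generated in code; no files).

# Small noiseless FRAP curve spec.
frap_spec <- function(seed = 1, f_imm = 0.3, tau = 2, bleach_depth = 0.5,
                      noise = noise_none(), model = "exponential", ...) {
  scene_spec("frap", seed = seed, f_imm = f_imm, tau = tau,
             bleach_depth = bleach_depth, noise = noise, model = model, ...)
}

# Normalize + fit one simulated exponential curve, returning the fit.
fit_sim_exponential <- function(seed, f_imm, noise = noise_none(),
                                n_pre = 10L, n_post = 100L, dt = 0.2) {
  cv <- simulate_frap_curve(frap_spec(seed = seed, f_imm = f_imm, noise = noise),
                            n_pre = n_pre, n_post = n_post, dt = dt)
  fit_frap_exponential(double_normalize(cv))
}

# Strip-bleach FRAP stack geometry used for mechanistic tests: the bleach
# strip spans the full image height so recovery is one-dimensional.
strip_frap_spec <- function(seed = 11, D = 0.3, shape = c(48L, 240L),
                            px = 0.1, w_um = 1, f_imm = 0,
                            noise = noise_none()) {
  w_px <- w_um / px
  roi <- roi_rect(x = (shape[2] - 1) / 2 - w_px / 2, y = -0.5,
                  width = w_px, height = shape[1], label = "bleach")
  scene_spec("frap", seed = seed, shape = shape, pixel_size_um = px,
             noise = noise, D = D, f_imm = f_imm, bleach_depth = 0.5,
             roi = roi, model = "ellenberg", w = w_um)
}

# Spot scene at the reference geometry: 5 um spots on a 10 um pitch,
# 0.2 um pixels, disjoint 4-um-radius cells centred on spots.
spot_scene <- function(seed = 3, ratio = 4, noise = noise_none(), n_cells = 3L) {
  generate_spot_scene(scene_spec("spots", seed = seed, pixel_size_um = 0.2,
                                 noise = noise, ratio = ratio,
                                 n_cells = n_cells))
}

run_spot_pipeline <- function(scene, background = 0) {
  spots <- segment_spots(get_frame(scene$stack, 1, "spots"),
                         spot_diameter_px = scene$spec$spot_diameter_um /
                           scene$spec$pixel_size_um)
  cells <- segment_cells(get_frame(scene$stack, 1, "dic"), min_area_px = 100L)
  spot_enrichment(get_frame(scene$stack, 1, "fluor"),
                  combine_masks(spots, cells), background = background)
}

synapse_timelapse <- function(seed = 5, speed = 0.05, coloc = 1,
                              n_clusters = 6L, noise = noise_none(),
                              n_frames = 30L, dt = 2) {
  generate_synapse_timelapse(
    scene_spec("synapse", seed = seed, shape = c(128L, 128L),
               pixel_size_um = 0.1, noise = noise, n_clusters = n_clusters,
               speed_um_s = speed, colocalized_fraction = coloc,
               cell_radius_um = 5),
    n_frames = n_frames, dt = dt)
}

# Line ROI along the transport path of cluster 1 (angle 0, +x direction),
# truncated away from the centre so the central cluster stays off the line.
cluster1_line <- function(shape = c(128L, 128L), px = 0.1) {
  cx <- (shape[2] - 1) / 2
  roi_line(cx + 0.8 / px, cx, cx + 4.6 / px, cx)
}
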