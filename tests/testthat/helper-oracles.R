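# Independent oracles, deliberately implemented without using the package's
# own numerics.

# Closed-form 1-D strip-bleach recovery value (scalar arithmetic).
ellenberg_value <- function(t, I_final, D, w) {
  I_final * (1 - sqrt(w^2 / (w^2 + 4 * pi * D * t)))
}

# Lattice random-walk particle simulation of a FRAP experiment: walkers on
# the pixel lattice take nearest-neighbour steps (move probability scaled so
# the walk's diffusion coefficient is exactly D), reflecting at the borders;
# the bleach removes walkers inside the ROI with probability `depth`.
# Returns the mean-concentration trace over the ROI for n_post frames
# (concentration 1 = prebleach uniform density), plus the per-frame binomial
# standard error.
frap_particle_trace <- function(shape, mask, D, px, depth, n_post, dt,
                                n_walkers = 1e5L, seed = 1L) {
  set.seed(seed)
  dt_sub <- px^2 / (4 * D)
  n_sub <- ceiling(dt / dt_sub)
  p_move <- 4 * D * (dt / n_sub) / px^2
  row <- sample.int(shape[1], n_walkers, replace = TRUE)
  col <- sample.int(shape[2], n_walkers, replace = TRUE)
  in_roi <- function() mask[cbind(row, col)]
  alive <- !(in_roi() & stats::runif(n_walkers) < depth)
  frac_roi <- sum(mask) / prod(shape)
  trace <- se <- numeric(n_post)
  for (f in seq_len(n_post)) {
    p_hat <- sum(alive & in_roi()) / n_walkers
    trace[f] <- p_hat / frac_roi
    se[f] <- sqrt(p_hat * (1 - p_hat) / n_walkers) / frac_roi
    if (f < n_post) {
      for (s in seq_len(n_sub)) {
        mv <- stats::runif(n_walkers) < p_move
        dir <- sample.int(4L, n_walkers, replace = TRUE)
        row <- pmin(pmax(row + c(1L, -1L, 0L, 0L)[dir] * mv, 1L), shape[1])
        col <- pmin(pmax(col + c(0L, 0L, 1L, -1L)[dir] * mv, 1L), shape[2])
      }
    }
  }
  list(trace = trace, se = se)
}
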