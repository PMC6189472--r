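test_that("scene specs validate their ground-truth fields", {
  expect_error(scene_spec("frap"), "seed")
  expect_error(scene_spec("frap", seed = 1, f_imm = 1.2), "0, 1")
  expect_error(scene_spec("spots", seed = 1, ratio = 0), "> 0")
  expect_error(scene_spec("frap", seed = 1, nonsense = 2), "Unknown")
})

test_that("identical scene specs give byte-identical outputs", {
  s1 <- simulate_frap_curve(frap_spec(seed = 5, noise = noise_gaussian(0.02)))
  s2 <- simulate_frap_curve(frap_spec(seed = 5, noise = noise_gaussian(0.02)))
  expect_identical(s1$bleach, s2$bleach)
  sc1 <- spot_scene(seed = 9, noise = noise_gaussian(1))
  sc2 <- spot_scene(seed = 9, noise = noise_gaussian(1))
  expect_identical(sc1$stack$data, sc2$stack$data)
  tl1 <- synapse_timelapse(seed = 4, noise = noise_gaussian(0.5), n_frames = 5L)
  tl2 <- synapse_timelapse(seed = 4, noise = noise_gaussian(0.5), n_frames = 5L)
  expect_identical(tl1$stack$data, tl2$stack$data)
})

test_that("closed-form FRAP curves honour their limits", {
  # full mobility: recovery reaches 1 at t >> tau
  cv <- simulate_frap_curve(frap_spec(f_imm = 0, tau = 1), n_post = 120L, dt = 0.1)
  expect_equal(tail(cv$bleach, 1), 1, tolerance = 1e-3)
  # fully immobile: flat at 1 - bleach_depth
  cv1 <- simulate_frap_curve(frap_spec(f_imm = 1, bleach_depth = 0.5))
  post <- cv1$bleach[cv1$t >= 0]
  expect_equal(post, rep(0.5, length(post)))
  expect_error(simulate_frap_curve(frap_spec(model = "nope")), "Unknown")
})

test_that("the ellenberg-form curve matches hand-computed values", {
  # w = 1 um, D = 0.25/pi um^2/s makes 4*pi*D*t = t: I = If*(1 - (1/(1+t))^0.5)
  spec <- frap_spec(f_imm = 0.2, model = "ellenberg", D = 0.25 / pi,
                    bleach_depth = 1, w = 1)
  cv <- simulate_frap_curve(spec, n_pre = 2L, n_post = 5L, dt = 1)
  post <- cv$bleach[cv$t >= 0]
  expected <- 0.8 * (1 - sqrt(1 / (1 + 0:4)))
  expect_equal(post, expected, tolerance = 1e-12)
})

test_that("reaction-diffusion stack conserves intensity and D = 0 stays flat", {
  spec <- strip_frap_spec(seed = 31, D = 0.3, shape = c(32L, 120L))
  st <- simulate_frap_stack(spec, n_pre = 2, n_post = 20, dt = 0.2)
  totals <- vapply(seq_len(n_frames(st)), function(f) sum(st$data[f, 1, , ]),
                   numeric(1))
  expect_lt(max(abs(totals[3:22] / totals[3] - 1)), 1e-3)
  frozen <- strip_frap_spec(seed = 31, D = 1e-12, shape = c(32L, 120L))
  st0 <- simulate_frap_stack(frozen, n_pre = 2, n_post = 10, dt = 0.2)
  tr <- roi_trace(st0, frozen$roi)$value
  expect_equal(tr[3:12], rep(tr[3], 10), tolerance = 1e-9)
})

test_that("spot scenes encode the prescribed enrichment exactly", {
  sc <- spot_scene(ratio = 4)
  fl <- get_frame(sc$stack, 1, "fluor")
  m <- sc$masks
  expect_equal(mean(fl[m$on_spot > 0]) / mean(fl[m$off_spot > 0]), 4)
  # uniform cell when ratio = 1
  sc1 <- spot_scene(ratio = 1)
  fl1 <- get_frame(sc1$stack, 1, "fluor")
  expect_equal(length(unique(fl1[sc1$masks$cells > 0])), 1L)
  # per-spot mask area close to the analytic disk area
  n_spots <- 3
  area <- sum(sc$masks$spots) / n_spots
  r_px <- sc$spec$spot_diameter_um / 2 / sc$spec$pixel_size_um
  expect_lt(abs(area - pi * r_px^2) / (pi * r_px^2), 0.05)
})

test_that("bead scenes yield equal-size ROIs and the exact prescribed ratio", {
  bs <- generate_bead_scene(scene_spec("bead", seed = 4, shape = c(96L, 96L),
                                       noise = noise_none(), ratio = 3))
  img <- get_frame(bs$stack, 1, 1)
  mc <- roi_mask(bs$contact, dim(img)); mo <- roi_mask(bs$opposite, dim(img))
  expect_identical(sum(mc), sum(mo))
  expect_equal(mean(img[mc]) / mean(img[mo]), 3)
  # ratio 1: both sides identical in the mean
  bs1 <- generate_bead_scene(scene_spec("bead", seed = 4, shape = c(96L, 96L),
                                        noise = noise_none(), ratio = 1))
  img1 <- get_frame(bs1$stack, 1, 1)
  expect_equal(mean(img1[roi_mask(bs1$contact, dim(img1))]),
               mean(img1[roi_mask(bs1$opposite, dim(img1))]))
})

test_that("synapse tracks move centripetally at the prescribed speed", {
  tl <- synapse_timelapse(seed = 2, speed = 0.05, n_frames = 20L, dt = 2)
  tr <- dplyr::filter(tl$tracks, .data$channel == "cd6", !.data$merged)
  rates <- tr |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(rate = -stats::coef(stats::lm(r_um ~ t))[[2]])
  expect_true(all(abs(rates$rate - 0.05) / 0.05 < 0.02))
  # static regime: all positions constant
  tl0 <- synapse_timelapse(seed = 2, speed = 0, n_frames = 10L)
  pos_per_cluster <- tl0$tracks |>
    dplyr::group_by(.data$channel, .data$cluster) |>
    dplyr::summarise(sd_x = stats::sd(x), sd_y = stats::sd(y), .groups = "drop")
  expect_true(all(pos_per_cluster$sd_x == 0 & pos_per_cluster$sd_y == 0))
})

test_that("colocalized_fraction = 1 makes the channel masks identical", {
  tl <- synapse_timelapse(seed = 3, coloc = 1, n_frames = 4L)
  for (f in c(1L, 4L)) {
    a <- threshold_channel(tl$stack$data[f, 1, , ])
    b <- threshold_channel(tl$stack$data[f, 2, , ])
    expect_identical(a$mask, b$mask)
  }
})
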