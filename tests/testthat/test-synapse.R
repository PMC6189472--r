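synapse_cond_spec <- function(seed = 7) {
  scene_spec("synapse", seed = seed, pixel_size_um = 0.2,
             noise = noise_none(), cell_radius_um = 4)
}

test_that("central clusters are called, peripheral and blank ones are not", {
  sc <- generate_synapse_condition(synapse_cond_spec(), n_cells = 2,
                                   csmac_present = c(TRUE, FALSE))
  cd3 <- get_frame(sc$stack, 1, "cd3")
  pos <- detect_csmac(cd3, sc$cells == 1L, pixel_size_um = 0.2)
  expect_true(pos$has_csmac)
  expect_gte(pos$csmac_area_um2, 3)
  neg <- detect_csmac(cd3, sc$cells == 2L, pixel_size_um = 0.2)
  expect_false(neg$has_csmac)
  expect_false(neg$centrality_pass)  # peripheral clusters fail centrality
  blank <- detect_csmac(matrix(0, 40, 40), matrix(TRUE, 40, 40))
  expect_false(blank$has_csmac)
})

test_that("lowering the area threshold never decreases the positive count", {
  sc <- generate_synapse_condition(synapse_cond_spec(seed = 19), n_cells = 6,
                                   csmac_present = rep(c(TRUE, FALSE), 3))
  counts <- vapply(c(8, 5, 3, 1, 0.2), function(a) {
    s <- score_condition(sc$stack, cells = sc$cells, min_area_um2 = a)
    s$n_positive
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("synapse fraction is recovered exactly on noiseless fixtures", {
  for (frac in c(0, 0.25, 0.5, 1)) {
    n <- 8L
    present <- rep(FALSE, n); present[seq_len(frac * n)] <- TRUE
    sc <- generate_synapse_condition(synapse_cond_spec(seed = 20), n_cells = n,
                                     csmac_present = present)
    score <- score_condition(sc$stack)
    expect_equal(score$fraction, frac)
    expect_equal(score$n_eligible, n)
    g <- glance(score)
    expect_true(g$ci_lower <= frac && frac <= g$ci_upper)
    expect_equal(nrow(tidy(score)), n)
  }
})

test_that("blocked transport lowers the synapse-forming fraction", {
  # same time-lapse geometry; a static (speed 0) scene keeps clusters
  # peripheral, a transporting scene coalesces them centrally
  score_from_timelapse <- function(speed, seed) {
    tl <- synapse_timelapse(seed = seed, speed = speed, coloc = 1,
                            n_frames = 25L, dt = 4)
    last <- get_frame(tl$stack, n_frames(tl$stack), "cd3")
    cell <- matrix(TRUE, 128, 128)
    # the merged cluster is compact (~0.3 um blobs): use a matched area floor
    detect_csmac(last, cell, pixel_size_um = 0.1,
                 min_area_um2 = 0.5)$has_csmac
  }
  expect_true(score_from_timelapse(0.05, seed = 22))
  expect_false(score_from_timelapse(0, seed = 22))
})

test_that("DiI eligibility excludes cells off the bilayer", {
  sc <- generate_synapse_condition(synapse_cond_spec(seed = 23), n_cells = 4,
                                   csmac_present = rep(TRUE, 4))
  # carve the bilayer away under cell 1
  dil <- get_frame(sc$stack, 1, "dil")
  dil[sc$cells == 1L] <- 0
  # rebuild a stack with the modified DiI channel
  arr <- sc$stack$data
  arr[1, 3, , ] <- dil
  st <- image_stack(arr, pixel_size_um = sc$stack$pixel_size_um,
                    channel_names = sc$stack$channel_names)
  score <- score_condition(st, cells = sc$cells)
  expect_equal(score$n_eligible, 3L)
  expect_equal(score$fraction, 1)
  expect_false(tidy(score)$eligible[1])
})

test_that("wilson interval is sane against binom.test on edge counts", {
  ci <- isquant:::wilson_ci(0, 20)
  expect_equal(ci[["lower"]], 0)
  expect_lt(ci[["upper"]], 0.2)
  ci2 <- isquant:::wilson_ci(10, 20)
  bt <- stats::binom.test(10, 20)$conf.int
  expect_lt(abs(ci2[["lower"]] - bt[1]), 0.05)
  expect_lt(abs(ci2[["upper"]] - bt[2]), 0.05)
})
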