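test_that("noiseless spot segmentation equals the generator ground truth", {
  sc <- spot_scene(ratio = 2)
  mask <- segment_spots(get_frame(sc$stack, 1, "spots"), spot_diameter_px = 25)
  expect_identical(mask, sc$masks$spots)
})

test_that("constant images give empty masks with warnings", {
  expect_warning(m <- segment_spots(matrix(3, 32, 32)), "empty")
  expect_false(any(m))
  expect_warning(l <- segment_cells(matrix(5, 32, 32)), "empty")
  expect_equal(max(l), 0L)
})

test_that("noisy spot segmentation stays close to ground truth (Jaccard)", {
  # sigma = 5% of the 0-100 spot-channel contrast
  sc <- spot_scene(seed = 17, ratio = 2, noise = noise_gaussian(5))
  mask <- segment_spots(get_frame(sc$stack, 1, "spots"), spot_diameter_px = 25)
  gt <- sc$masks$spots
  jaccard <- sum(mask & gt) / sum(mask | gt)
  expect_gte(jaccard, 0.95)
})

test_that("cell segmentation finds disjoint cells with high overlap", {
  sc <- spot_scene(seed = 3, ratio = 2)
  cells <- segment_cells(get_frame(sc$stack, 1, "dic"), min_area_px = 100L)
  gt <- sc$masks$cells
  expect_equal(max(cells), 3L)
  for (i in 1:3) {
    iou <- max(vapply(seq_len(max(cells)), function(j) {
      sum(gt == i & cells == j) / sum(gt == i | cells == j)
    }, numeric(1)))
    expect_gte(iou, 0.9)
  }
  # a size filter above every cell removes all labels
  expect_warning(none <- segment_cells(get_frame(sc$stack, 1, "dic"),
                                       min_area_px = 10000L), "size filter")
  expect_equal(max(none), 0L)
})

test_that("mask combination partitions every cell exactly", {
  sc <- spot_scene(ratio = 2)
  ms <- combine_masks(sc$masks$spots, sc$masks$cells)
  expect_identical((ms$on_spot > 0) & (ms$off_spot > 0),
                   matrix(FALSE, nrow(ms$cells), ncol(ms$cells)))
  expect_identical(pmax(ms$on_spot, ms$off_spot), ms$cells)
  # spots empty -> everything off-spot; spots everywhere -> everything on-spot
  empty <- combine_masks(matrix(FALSE, nrow(ms$cells), ncol(ms$cells)), sc$masks$cells)
  expect_equal(sum(empty$on_spot), 0)
  expect_identical(empty$off_spot, sc$masks$cells)
  all_on <- combine_masks(matrix(TRUE, nrow(ms$cells), ncol(ms$cells)), sc$masks$cells)
  expect_equal(sum(all_on$off_spot), 0)
})

test_that("spot segmentation is idempotent on its own output", {
  sc <- spot_scene(ratio = 2)
  m1 <- segment_spots(get_frame(sc$stack, 1, "spots"), spot_diameter_px = 25)
  m2 <- segment_spots(m1 * 1, spot_diameter_px = 25)
  expect_identical(m2, m1)
})

test_that("noiseless enrichment equals the prescribed ratio across regimes", {
  for (r in c(0.25, 0.5, 1, 2, 4, 10)) {
    sc <- spot_scene(seed = 23, ratio = r)
    enr <- spot_enrichment(get_frame(sc$stack, 1, "fluor"), sc$masks)
    expect_equal(enr$ratio, rep(r, 3), tolerance = 1e-6)
  }
})

test_that("enrichment is invariant under multiplicative gain", {
  sc <- spot_scene(seed = 29, ratio = 4, noise = noise_gaussian(1))
  fl <- get_frame(sc$stack, 1, "fluor")
  e1 <- spot_enrichment(fl, sc$masks, background = 2)
  e2 <- spot_enrichment(fl * 5, sc$masks, background = 10)
  expect_equal(e1$ratio, e2$ratio, tolerance = 1e-12)
})

test_that("slivers and sub-background cells are excluded or flagged", {
  cells <- matrix(0L, 20, 20); cells[5:15, 5:15] <- 1L
  spots <- matrix(FALSE, 20, 20); spots[10, 10] <- TRUE  # 1-px on-spot region
  img <- matrix(50, 20, 20)
  enr <- spot_enrichment(img, combine_masks(spots, cells), min_pixels = 20)
  expect_true(enr$excluded)
  expect_true(is.na(enr$ratio))
  # off-spot at background level -> flagged, not a ratio
  spots2 <- matrix(FALSE, 20, 20); spots2[5:15, 5:10] <- TRUE
  img2 <- img; img2[cells == 1L & !spots2] <- 10
  enr2 <- spot_enrichment(img2, combine_masks(spots2, cells),
                          background = 10, min_pixels = 5)
  expect_identical(enr2$flag, "off_spot_at_or_below_background")
})

test_that("bead enrichment handles identical ROIs, fixtures and errors", {
  img <- matrix(runif(64 * 64) + 1, 64, 64)
  r <- roi_rect(10, 10, 8, 8)
  expect_equal(bead_enrichment(img, r, r)$ratio, 1)
  bs <- generate_bead_scene(scene_spec("bead", seed = 4, shape = c(96L, 96L),
                                       noise = noise_none(), ratio = 3))
  be <- bead_enrichment(get_frame(bs$stack, 1, 1), bs$contact, bs$opposite)
  expect_equal(be$ratio, 3, tolerance = 1e-9)
  expect_identical(be$n_contact, be$n_opposite)
  # opposite ROI in a zero region -> error
  zero_img <- matrix(0, 96, 96)
  expect_error(bead_enrichment(zero_img, bs$contact, bs$opposite), "background")
  # mismatched ROI sizes warn
  expect_warning(
    bead_enrichment(get_frame(bs$stack, 1, 1), bs$contact,
                    roi_rect(4, 4, 30, 30, "big")),
    "differ")
})
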