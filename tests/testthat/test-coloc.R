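test_that("thresholding methods behave as specified", {
  # bimodal image: Otsu keeps the bright mode
  img <- matrix(c(rep(10, 60), rep(200, 40)), 10, 10)
  th <- threshold_channel(img, "otsu")
  expect_identical(th$mask, img >= th$threshold)
  expect_equal(sum(th$mask), 40)
  # percentile 99 on a ramp of distinct values keeps exactly 1% of pixels
  ramp <- matrix(seq_len(100 * 100), 100, 100)
  tp <- threshold_channel(ramp, "percentile", p = 99)
  expect_equal(sum(tp$mask), 100)
  # fixed threshold is literal
  tf <- threshold_channel(ramp, "fixed", value = 5000)
  expect_identical(tf$mask, ramp >= 5000)
  expect_error(threshold_channel(matrix(1, 4, 4), "otsu"), "fixed")
})

test_that("manders coefficients satisfy their boundary identities", {
  withr::local_seed(31)
  A <- matrix(runif(400, 1, 2), 20, 20)
  B <- matrix(runif(400, 1, 2), 20, 20)
  mask <- matrix(FALSE, 20, 20); mask[3:12, 3:12] <- TRUE
  same <- manders(A, B, mask, mask)
  expect_equal(same$m1, 1); expect_equal(same$m2, 1)
  other <- matrix(FALSE, 20, 20); other[15:18, 15:18] <- TRUE
  disj <- manders(A, B, mask, other)
  expect_equal(disj$m1, 0); expect_equal(disj$m2, 0)
  # A uniform on 2n pixels, B-mask covering n of them -> M1 = 0.5
  A2 <- matrix(0, 20, 20); A2[1:10, 1] <- 3; A2[1:10, 2] <- 3
  mA <- A2 > 0
  mB <- matrix(FALSE, 20, 20); mB[1:10, 1] <- TRUE
  expect_equal(manders(A2, B, mA, mB)$m1, 0.5)
  # zero denominator flagged
  none <- manders(A * 0, B, mask, mask)
  expect_true(is.na(none$m1))
  expect_identical(none$flag, "zero_denominator")
})

test_that("channel swap exchanges M1 and M2 exactly", {
  withr::local_seed(5)
  A <- matrix(rexp(900), 30, 30); B <- matrix(rexp(900), 30, 30)
  mA <- A > quantile(A, 0.7); mB <- B > quantile(B, 0.8)
  ab <- manders(A, B, mA, mB)
  ba <- manders(B, A, mB, mA)
  expect_identical(ab$m1, ba$m2)
  expect_identical(ab$m2, ba$m1)
  expect_true(all(c(ab$m1, ab$m2) >= 0 & c(ab$m1, ab$m2) <= 1))
})

test_that("manders with percentile thresholding is gain-invariant", {
  withr::local_seed(6)
  A <- matrix(rexp(900), 30, 30); B <- matrix(rexp(900), 30, 30)
  mA <- threshold_channel(A, "percentile", p = 90)$mask
  mB <- threshold_channel(B, "percentile", p = 90)$mask
  mA2 <- threshold_channel(A * 7, "percentile", p = 90)$mask
  mB2 <- threshold_channel(B * 0.3, "percentile", p = 90)$mask
  expect_equal(manders(A, B, mA, mB)[1:2],
               manders(A * 7, B * 0.3, mA2, mB2)[1:2], tolerance = 1e-12)
})

test_that("pearson correlation hits its exact and statistical bounds", {
  withr::local_seed(41)
  A <- matrix(runif(10000), 100, 100)
  expect_equal(coloc_pearson(A, A), 1)
  expect_equal(coloc_pearson(A, -A + 5), -1)
  B <- matrix(runif(10000), 100, 100)
  expect_lt(abs(coloc_pearson(A, B)), 0.05)
  expect_warning(r <- coloc_pearson(A, matrix(1, 100, 100)), "variance")
  expect_true(is.na(r))
})

test_that("co-localization time series track the ground-truth overlap", {
  co1 <- coloc_timeseries(synapse_timelapse(seed = 8, coloc = 1, n_frames = 8L)$stack)
  expect_true(all(co1$m1 >= 0.95))
  co0 <- coloc_timeseries(synapse_timelapse(seed = 8, coloc = 0, n_frames = 8L)$stack)
  expect_true(all(co0$m1 <= 0.05))
})

test_that("M1 rises as clusters are transported into the centre", {
  tl <- synapse_timelapse(seed = 9, coloc = 0.5, speed = 0.05,
                          n_frames = 30L, dt = 2)
  co <- coloc_timeseries(tl$stack)
  first_third <- mean(co$m1[1:10]); last_third <- mean(co$m1[21:30])
  expect_gt(last_third, first_third)
  expect_gte(stats::coef(stats::lm(m1 ~ t, co))[[2]], 0)
})

test_that("relative integrated density is 1 at the reference time", {
  tl <- synapse_timelapse(seed = 10, speed = 0.05, n_frames = 20L, dt = 2)
  roi <- roi_circle((128 - 1) / 2, (128 - 1) / 2, 12, "centre")
  rel <- relative_intensity_timeseries(tl$stack, "cd6", roi, t_ref = 10)
  expect_equal(rel$relative[rel$t == 10], 1)
  # doubling the stack contents doubles the relative value elsewhere
  st2 <- tl$stack; st2$data <- st2$data * 2
  rel2 <- relative_intensity_timeseries(st2, "cd6", roi, t_ref = 10)
  expect_equal(rel2$relative, rel$relative, tolerance = 1e-12)
  # central accumulation: relative signal rises over the series
  expect_gt(mean(tail(rel$relative, 5)), mean(head(rel$relative, 5)))
  expect_error(relative_intensity_timeseries(tl$stack, "cd6", roi, t_ref = 1e5),
               "duration")
})
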