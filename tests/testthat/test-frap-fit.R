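test_that("noiseless exponential curves are recovered exactly", {
  fit <- fit_sim_exponential(seed = 1, f_imm = 0.3)
  expect_true(fit$converged)
  expect_equal(fit$mobile_fraction, 0.7, tolerance = 1e-6)
  expect_equal(fit$tau, 2, tolerance = 1e-6)
  expect_equal(fit$t_half, log(2) * fit$tau)
  td <- tidy(fit)
  expect_identical(td$term, c("A", "tau"))
  expect_equal(td$estimate[1], 0.7, tolerance = 1e-6)
})

test_that("tau = 1 gives the ln-2 halftime", {
  cv <- simulate_frap_curve(frap_spec(seed = 5, f_imm = 0, tau = 1))
  fit <- fit_frap_exponential(double_normalize(cv))
  expect_equal(fit$t_half, 0.6931, tolerance = 1e-4)
})

test_that("noiseless ellenberg curves are recovered exactly", {
  spec <- frap_spec(seed = 6, f_imm = 0.2, model = "ellenberg", D = 0.1, w = 1)
  cv <- simulate_frap_curve(spec, n_pre = 5, n_post = 300, dt = 0.1)
  fit <- fit_frap_ellenberg(single_normalize(cv), w = 1)
  expect_true(fit$converged)
  expect_equal(fit$mobile_fraction, 0.8, tolerance = 1e-6)
  expect_equal(fit$D, 0.1, tolerance = 1e-6)
})

test_that("the two ellenberg halftimes are both reported and differ by ~7.9%", {
  spec <- frap_spec(seed = 7, f_imm = 0, model = "ellenberg", D = 0.22, w = 1)
  cv <- simulate_frap_curve(spec, n_pre = 5, n_post = 400, dt = 0.05)
  fit <- fit_frap_ellenberg(single_normalize(cv), w = 1)
  # 0.88-convention halftime: t_half = 0.88 w^2 / (4 D) = 1 s at D = 0.22
  expect_equal(fit$t_half, 1, tolerance = 1e-5)
  # exact model halftime by independent root-solve of F(t) = I_final / 2
  root <- uniroot(function(t) ellenberg_value(t, 1, 0.22, 1) - 0.5,
                  c(0.1, 10), tol = 1e-12)$root
  expect_equal(fit$t_half_exact, root, tolerance = 1e-9)
  expect_equal(root, 3 / (4 * pi * 0.22), tolerance = 1e-9)
  rel <- (fit$t_half_exact - fit$t_half) / fit$t_half_exact
  expect_equal(rel, 1 - 0.22 / (3 / (4 * pi)), tolerance = 1e-6)
  expect_gt(rel, 0.07); expect_lt(rel, 0.09)
})

test_that("immobile-fraction recovery is unbiased over the study grid", {
  # 100 noisy curves per level; |bias| <= 0.02 and SD <= 0.05
  for (f_imm in c(0, 0.1, 0.3, 0.5)) {
    imm <- vapply(seq_len(100), function(s) {
      fit_sim_exponential(seed = 7000 + s, f_imm = f_imm,
                          noise = noise_gaussian(0.02))$immobile_fraction
    }, numeric(1))
    expect_lt(abs(mean(imm) - f_imm), 0.02)
    expect_lt(sd(imm), 0.05)
  }
})

test_that("non-convergence is flagged, never silent", {
  bad <- structure(
    tibble::tibble(t = c(0, 1, 2, 3, 4, 5),
                   intensity = c(0, NA, NA, NA, NA, NA),
                   intensity_prebleach = 1),
    class = c("frap_curve", "tbl_df", "tbl", "data.frame"),
    scale = "full_scale")
  fit <- fit_frap_exponential(bad)
  expect_false(fit$converged)
  expect_true(is.character(fit$message) && !is.na(fit$message))
  expect_false(glance(fit)$converged)
})

test_that("group summaries report median, IQR and convergence", {
  fits <- lapply(c(0.1, 0.2, 0.3), function(a) {
    cv <- simulate_frap_curve(frap_spec(seed = 50 + a * 10, f_imm = 1 - a))
    fit_frap_exponential(double_normalize(cv))
  })
  sm <- summarize_frap_group(fits)
  mf <- sm[sm$parameter == "mobile_fraction", ]
  expect_equal(mf$median, 0.2, tolerance = 1e-6)
  expect_equal(mf$n, 3L)
  expect_equal(mf$frac_converged, 1)
  one <- summarize_frap_group(fits[2])
  expect_equal(one[one$parameter == "tau", ]$median, fits[[2]]$tau)
})
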