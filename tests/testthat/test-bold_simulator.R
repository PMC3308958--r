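# Block design, canonical HRF, forward simulation, PSF model.

test_that("default block design has 168 TRs and the stated block structure", {
  d <- make_block_design(TR = 2, block_s = 16, cycles = 10.5)
  expect_identical(d$n_time, 168L)
  expect_identical(length(d$block_labels), 21L)
  expect_identical(d$block_labels[1], "stim")    # starts with stimulus
  expect_identical(d$block_labels[21], "stim")   # the half cycle ends on one
  # one-cycle run starting with stimulus: eight 1s then eight 0s
  d1 <- make_block_design(cycles = 1)
  expect_equal(d1$boxcars[, 1], c(rep(1, 8), rep(0, 8)))
  expect_error(make_block_design(TR = 3, block_s = 16), "divide")
})

test_that("canonical HRF has the contracted length, sum and peak", {
  h <- canonical_hrf(TR = 2)
  expect_identical(length(h), 17L)      # t = 0..32 s inclusive
  expect_equal(sum(h), 1)
  hf <- canonical_hrf(TR = 0.1)
  tf <- seq(0, 32, by = 0.1)
  expect_equal(tf[which.max(hf)], 5, tolerance = 0.1)
})

test_that("zero-amplitude noiseless sessions are constant in time", {
  ph <- flat_phantom(fov = c(4, 4, 8), edge = 1)
  sess <- simulate_session(ph$tissue, ph$truth, const_profile(amp = 0),
                           make_block_design(), noise_sd = 0, psf_fwhm_mm = 0)
  rng <- apply(sess$data, 1:3, function(v) diff(range(v)))
  expect_true(all(rng == 0))
})

test_that("noiseless blur-free modulation inverts through the GLM exactly", {
  ph <- flat_phantom(fov = c(4, 4, 8), edge = 1)
  design <- make_block_design()
  sess <- simulate_session(ph$tissue, ph$truth, const_profile(amp = 1),
                           design, noise_sd = 0, psf_fwhm_mm = 0)
  ts <- sess$data[2, 2, ph$truth$k[1], ]
  reg <- apply(convolve_design(design), 2, highpass_filter)
  g <- fit_glm(highpass_filter(ts), reg)
  expect_equal(g$amplitude, 1, tolerance = 1e-7)
  # two interleaved conditions with different amplitudes, as in the M/P runs
  d2 <- make_block_design(cycles = 8, conditions = c("P", "M"))
  fns <- list(P = function(d) rep(1.2, length(d)),
              M = function(d) rep(0.6, length(d)))
  p2 <- neural_depth_profile(amplitude = fns,
                             baseline_bias = function(d) rep(1, length(d)))
  s2 <- simulate_session(ph$tissue, ph$truth, p2, d2, noise_sd = 0,
                         psf_fwhm_mm = 0)
  ts2 <- s2$data[2, 2, ph$truth$k[1], ]
  g2 <- fit_glm(highpass_filter(ts2),
                apply(convolve_design(d2), 2, highpass_filter))
  expect_equal(g2$amplitude[g2$condition == "P"], 1.2, tolerance = 1e-7)
  expect_equal(g2$amplitude[g2$condition == "M"], 0.6, tolerance = 1e-7)
})

test_that("amplitude recovery is unbiased under AR(1) noise", {
  ph <- flat_phantom(fov = c(4, 4, 8), edge = 1)
  design <- make_block_design()
  reg <- apply(convolve_design(design), 2, highpass_filter)
  est <- vapply(1:40, function(s) {
    sess <- simulate_session(ph$tissue, ph$truth, const_profile(amp = 1),
                             design, noise_sd = 0.5, noise_ar = 0.3,
                             psf_fwhm_mm = 0, seed = s)
    ts <- sess$data[2, 2, ph$truth$k[1], ]
    fit_glm(highpass_filter(ts), reg)$amplitude
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 1), 2 * mc_se + 0.02)
})

test_that("sessions are reproducible from the seed", {
  ph <- flat_phantom(fov = c(4, 4, 8), edge = 1)
  d <- make_block_design()
  s1 <- simulate_session(ph$tissue, ph$truth, const_profile(), d, seed = 5)
  s2 <- simulate_session(ph$tissue, ph$truth, const_profile(), d, seed = 5)
  expect_identical(s1$data, s2$data)
})

test_that("PSF blur monotonically attenuates laminar contrast", {
  ph <- curved_phantom(fov = c(10, 10, 8), fold_amp = 1, fold_wavelength = 12)
  design <- make_block_design(cycles = 4,
                              conditions = c("intact", "scrambled"))
  band <- mid_bin_band(ph$truth$rel_depth, 5)
  contrasts <- vapply(c(0, 0.6, 1.2), function(fw) {
    sess <- simulate_session(ph$tissue, ph$truth,
                             two_cond_profile(band = band), design,
                             noise_sd = 0, psf_fwhm_mm = fw)
    prof <- laminar_profile(sess, ph$truth, k = 5)
    dp <- differential_profile(prof, "scrambled", "intact")
    max(dp$diff) - min(dp$diff)
  }, numeric(1))
  expect_true(all(diff(contrasts) < 0))
})

test_that("a deep-to-superficial latency gradient yields a monotone profile", {
  ph <- curved_phantom(fov = c(10, 10, 8), fold_amp = 1, fold_wavelength = 12)
  d10 <- make_block_design(cycles = 10)
  # 0.1 s per depth quintile, deep to superficial (0.4 s total range)
  qb <- quantile(ph$truth$rel_depth, seq(0.2, 0.8, by = 0.2))
  lat_step <- function(d) 0.1 * findInterval(d, qb)
  prof <- neural_depth_profile(
    amplitude = list(stim = function(d) rep(1, length(d))),
    latency = list(stim = lat_step),
    baseline_bias = function(d) rep(1, length(d)))
  sess <- simulate_session(ph$tissue, ph$truth, prof, d10, noise_sd = 0,
                           psf_fwhm_mm = 0)
  lb <- latency_by_depth(list(sess), ph$truth, k = 5)
  expect_true(all(diff(lb$raw[1, ]) > 0))
  expect_equal(diff(range(lb$raw[1, ])), 0.4, tolerance = 0.05)
})

test_that("cube projection profile is a unit-area boxcar along an axis", {
  ax <- psf_fwhm_estimate(directions = matrix(c(1, 0, 0), 1))
  expect_equal(as.numeric(ax), 1, tolerance = 0.01)
  prof <- attr(ax, "profile"); tg <- attr(ax, "grid")
  expect_equal(sum(prof) * diff(tg)[1], 1, tolerance = 1e-6)
  # random-orientation average also integrates to 1
  f <- psf_fwhm_estimate(2000, seed = 1)
  expect_equal(sum(attr(f, "profile")) * diff(attr(f, "grid"))[1], 1,
               tolerance = 1e-6)
})
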