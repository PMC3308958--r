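# Depth binning, profiles, clusters, eligibility, ANOVA, paired tests.

test_that("equal-population binning follows the remainder rule and sort order", {
  b <- bin_by_depth(runif(100), k = 5)
  expect_equal(unname(table(b)), rep(20L, 5), ignore_attr = TRUE)
  b7 <- bin_by_depth(c(0.9, 0.1, 0.5, 0.3, 0.7, 0.2, 0.6), k = 5)
  expect_equal(unname(as.integer(table(b7))), c(2L, 2L, 1L, 1L, 1L))
  # sorted-contiguity invariant on random draws
  set.seed(2)
  for (rep in 1:20) {
    x <- runif(sample(10:200, 1))
    k <- sample(3:6, 1)
    bb <- bin_by_depth(x, k)
    for (i in seq_len(k - 1))
      expect_lte(max(x[bb == i]), min(x[bb == i + 1]))
  }
  expect_error(bin_by_depth(runif(3), 5), "fewer voxels")
})

test_that("laminar profiles are flat for constant truth and localized for banded truth", {
  ph <- curved_phantom(fov = c(10, 10, 8), fold_amp = 1, fold_wavelength = 12)
  design <- make_block_design(cycles = 6)
  sess <- simulate_session(ph$tissue, ph$truth, const_profile(amp = 1),
                           design, noise_sd = 0, psf_fwhm_mm = 0)
  prof <- laminar_profile(sess, ph$truth, k = 5)
  gm <- prof[prof$bin > 0, ]
  expect_equal(gm$amplitude, rep(1, 5), tolerance = 1e-6)
  expect_true(all(diff(gm$mean_depth) > 0))
  expect_true(all(abs(diff(gm$n_voxels)) <= 1))
  # middle-bin-only truth: [0, 0, amp, 0, 0]
  band <- mid_bin_band(ph$truth$rel_depth, 5)
  fns <- list(stim = function(d) 1 * (d >= band[1] & d < band[2]))
  pm <- neural_depth_profile(amplitude = fns,
                             baseline_bias = function(d) rep(1, length(d)))
  sm <- simulate_session(ph$tissue, ph$truth, pm, design, noise_sd = 0,
                         psf_fwhm_mm = 0)
  pf <- laminar_profile(sm, ph$truth, k = 5)
  gmm <- pf[pf$bin > 0, ]
  expect_equal(gmm$amplitude, c(0, 0, 1, 0, 0), tolerance = 1e-6)
  # WM reference present and unmodulated
  wm <- prof[prof$bin == 0, ]
  expect_identical(nrow(wm), 1L)
  expect_equal(wm$amplitude, 0, tolerance = 1e-6)
})

test_that("connected-component labeling obeys size and connectivity rules", {
  d <- c(12, 12, 12)
  mk <- function(vox) { m <- array(FALSE, d); m[vox] <- TRUE; m }
  # one 150-voxel blob -> one component of 150
  blob1 <- which(array(seq_len(prod(d)), d) > 0)[1:150]   # contiguous column run
  lab <- label_components(mk(blob1))
  expect_identical(max(lab), 1L)
  expect_identical(sum(lab == 1L), 150L)
  # two blobs separated by a subthreshold gap -> two components
  m <- array(FALSE, d)
  m[2:4, 2:4, 2:4] <- TRUE
  m[8:10, 8:10, 8:10] <- TRUE
  lab2 <- label_components(m)
  expect_identical(max(lab2), 2L)
  # diagonal touch is not face connectivity
  m3 <- array(FALSE, d)
  m3[1, 1, 1] <- TRUE; m3[2, 2, 1] <- TRUE
  expect_identical(max(label_components(m3)), 2L)
})

test_that("cluster detection enforces the 100-voxel minimum extent", {
  ph <- curved_phantom(fov = c(12, 12, 8), fold_amp = 1, fold_wavelength = 14)
  design <- make_block_design(cycles = 6)
  prof0 <- const_profile(amp = 0)
  sess <- simulate_session(ph$tissue, ph$truth, prof0, design, noise_sd = 0.4,
                           psf_fwhm_mm = 0, seed = 8)
  # inject a strong localized blob
  act <- (ph$truth$x - 6)^2 + (ph$truth$y - 6)^2 < 7
  lin <- linear_index(ph$tissue, ph$truth)
  reg <- convolve_design(design)[, 1]
  nv <- prod(ph$tissue$dims)
  for (t in seq_len(design$n_time))
    sess$data[lin[act] + (t - 1) * nv] <-
      sess$data[lin[act] + (t - 1) * nv] + 2 * reg[t]
  cl <- detect_clusters(sess, ph$truth, nperm = 300, p_thresh = 0.005,
                        min_voxels = 100, seed = 2)
  expect_identical(length(cl), 1L)
  expect_gte(cl[[1]]$size, 100L)
  expect_gt(length(cl[[1]]$wm_adjacent), 0L)
  # raising the extent threshold above the blob size empties the list
  cl2 <- detect_clusters(sess, ph$truth, nperm = 300, p_thresh = 0.005,
                         min_voxels = cl[[1]]$size + 1L, seed = 2)
  expect_identical(length(cl2), 0L)
})

test_that("ROI eligibility applies the WM-stability, bin-size and presence rules", {
  mkprof <- function(wm_a, wm_b, nvox) {
    rbind(
      data.frame(bin = 0, mean_depth = NA, n_voxels = 30,
                 condition = c("intact", "scrambled"),
                 amplitude = c(wm_a, wm_b), se = 0.02),
      do.call(rbind, lapply(1:5, function(b)
        data.frame(bin = b, mean_depth = b / 5 - 0.1, n_voxels = nvox,
                   condition = c("intact", "scrambled"),
                   amplitude = c(1, 1.2), se = 0.05))))
  }
  ok <- roi_eligibility(mkprof(0.10, 0.05, 70), presence_fraction = 0.4)
  expect_true(ok$eligible)
  expect_identical(ok$condition_preference, "scrambled")
  bad_wm <- roi_eligibility(mkprof(0.30, 0.05, 70), presence_fraction = 0.4)
  expect_false(bad_wm$eligible)
  expect_equal(bad_wm$wm_delta, 0.25)
  small <- roi_eligibility(mkprof(0.1, 0.05, 30), presence_fraction = 0.4)
  expect_false(small$eligible)       # 30 voxels/bin < 40
  absent <- roi_eligibility(mkprof(0.1, 0.05, 70), presence_fraction = 0.2)
  expect_false(absent$eligible)
  # data-driven threshold widens the constant rule
  wide <- roi_eligibility(mkprof(0.30, 0.05, 70), presence_fraction = 0.4,
                          mean_se = 0.15)
  expect_true(wide$eligible)         # threshold max(0.16, 0.30)
})

test_that("differential profiles subtract bin-wise and are antisymmetric", {
  prof <- do.call(rbind, lapply(1:5, function(b)
    data.frame(bin = b, mean_depth = b / 5 - 0.1, n_voxels = 50,
               condition = c("intact", "scrambled"),
               amplitude = c(1, c(1, 1, 2, 1, 1)[b]), se = 0.1)))
  dp <- differential_profile(prof, "intact", "scrambled")
  expect_equal(dp$diff, c(0, 0, -1, 0, 0))
  expect_equal(dp$se, rep(sqrt(0.02), 5))
  swap <- differential_profile(prof, "scrambled", "intact")
  expect_equal(swap$diff, -dp$diff)
  expect_error(differential_profile(prof, "intact", "absent"), "missing")
})

test_that("depth ANOVA reproduces the printed degrees of freedom and F", {
  set.seed(4)
  for (r in c(7, 4, 3)) {
    v <- matrix(rnorm(r * 5), r, 5)
    a <- depth_anova(v)
    expect_identical(a$df1, 4L)
    expect_identical(a$df2, as.integer(r * 5 - 5))
    # brute-force sums of squares oracle
    grand <- mean(v)
    ss_b <- r * sum((colMeans(v) - grand)^2)
    ss_w <- sum(sweep(v, 2, colMeans(v))^2)
    f_oracle <- (ss_b / 4) / (ss_w / (r * 5 - 5))
    expect_equal(a$F, f_oracle, tolerance = 1e-10)
  }
  # equal column means with nonzero within-bin variance -> F = 0
  v0 <- matrix(rnorm(15), 3, 5)
  v0 <- sweep(v0, 2, colMeans(v0))
  expect_equal(depth_anova(v0)$F, 0, tolerance = 1e-20)
  expect_error(depth_anova(matrix(1, 1, 5)), "at least 2")
})

test_that("per-depth paired t-tests use the doubled Bonferroni factor", {
  a <- matrix(rnorm(40), 8, 5)
  same <- paired_t_by_depth(a, a)
  expect_equal(same$t, rep(0, 5))
  expect_equal(same$p_corrected, rep(1, 5))
  b <- a; b[, 5] <- b[, 5] + 2      # strong superficial effect
  res <- paired_t_by_depth(a, b)
  expect_equal(res$p_corrected[res$p * 10 < 1],
               res$p[res$p * 10 < 1] * 10)   # factor 10 for k = 5
  expect_true(res$sig05[5])
  expect_error(paired_t_by_depth(a[1, , drop = FALSE], b[1, , drop = FALSE]),
               "at least 2")
})

test_that("condition-swap antisymmetry holds end to end on simulation", {
  ph <- curved_phantom(fov = c(10, 10, 8), fold_amp = 1, fold_wavelength = 12)
  design <- make_block_design(cycles = 6, conditions = c("intact", "scrambled"))
  sess <- simulate_session(ph$tissue, ph$truth,
                           two_cond_profile(band = mid_bin_band(ph$truth$rel_depth, 5)),
                           design, noise_sd = 0.3, psf_fwhm_mm = 0.6, seed = 6)
  prof <- laminar_profile(sess, ph$truth, k = 5)
  d1 <- differential_profile(prof, "intact", "scrambled")
  d2 <- differential_profile(prof, "scrambled", "intact")
  expect_equal(d1$diff, -d2$diff)
})

test_that("extremum depth is stable across 3-6 bins", {
  ph <- curved_phantom(fov = c(12, 12, 8), fold_amp = 1, fold_wavelength = 14)
  design <- make_block_design(cycles = 6, conditions = c("intact", "scrambled"))
  sess <- simulate_session(ph$tissue, ph$truth,
                           two_cond_profile(band = c(0.4, 0.6)), design,
                           noise_sd = 0.3, psf_fwhm_mm = 0.87 * 0.7, seed = 11)
  ext_depth <- vapply(3:6, function(k) {
    prof <- laminar_profile(sess, ph$truth, k = k)
    dp <- differential_profile(prof, "scrambled", "intact")
    dp$mean_depth[which.max(dp$diff)]
  }, numeric(1))
  expect_true(max(ext_depth) - min(ext_depth) <= 1 / 3 + 1e-9)
  expect_true(all(ext_depth > 0.25 & ext_depth < 0.75))
})

test_that("latency profiles are mean-centered and flat for constant latency", {
  ph <- flat_phantom(fov = c(6, 6, 8), edge = 0.5)
  d10 <- make_block_design(cycles = 10)
  sess <- simulate_session(ph$tissue, ph$truth, const_profile(lat = 0.3),
                           d10, noise_sd = 0, psf_fwhm_mm = 0)
  lb <- latency_by_depth(list(sess, sess), ph$truth, k = 5)
  expect_equal(unname(rowSums(lb$latency)), c(0, 0), tolerance = 1e-9)
  expect_lt(diff(range(lb$raw[1, ])), 1e-6)
})
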