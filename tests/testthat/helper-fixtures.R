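# Shared fixtures: small phantoms and sessions, built in code at test time.

flat_phantom <- function(fov = c(7, 7, 8), thickness = 2.5, edge = 0.5,
                         voxel = 0.7) {
  pc <- phantom_config(fov = fov, voxel = voxel, fold_amp = 0,
                       thickness = thickness, edge = edge)
  pair <- make_ribbon_phantom(pc)
  c(list(config = pc, pair = pair), voxelize(pair, pc))
}

curved_phantom <- function(fov = c(14, 14, 8), fold_amp = 1.5,
                           fold_wavelength = 14, edge = 0.35, voxel = 0.7) {
  pc <- phantom_config(fov = fov, voxel = voxel, fold_amp = fold_amp,
                       fold_wavelength = fold_wavelength, edge = edge)
  pair <- make_ribbon_phantom(pc)
  c(list(config = pc, pair = pair), voxelize(pair, pc))
}

# constant-amplitude single-condition profile with optional constant latency
const_profile <- function(amp = 1, lat = 0, condition = "stim", bias = 1) {
  fns <- list(function(d) rep(amp, length(d)))
  names(fns) <- condition
  lfns <- list(function(d) rep(lat, length(d)))
  names(lfns) <- condition
  neural_depth_profile(amplitude = fns, latency = lfns,
                       baseline_bias = function(d) rep(bias, length(d)))
}

# amplitude confined to the middle equal-population depth bin of `depths`
mid_bin_band <- function(depths, k = 5) {
  s <- sort(depths)
  n <- length(s)
  lo <- s[ceiling(2 * n / k)]
  hi <- s[ceiling(3 * n / k)]
  c((lo + s[ceiling(2 * n / k) + 1]) / 2, hi + 1e-9)
}

# two-condition profile: base amplitude everywhere, excess for cond2 within
# a relative-depth band
two_cond_profile <- function(base = 1, excess = 0.5, band = c(0.4, 0.6),
                             conds = c("intact", "scrambled")) {
  fns <- list(function(d) rep(base, length(d)),
              function(d) base + excess * (d >= band[1] & d < band[2]))
  names(fns) <- conds
  neural_depth_profile(amplitude = fns,
                       baseline_bias = function(d) rep(1, length(d)))
}

linear_index <- function(tissue, truth) {
  laminarfmri:::voxel_linear_index(tissue, truth$i, truth$j, truth$k)
}
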