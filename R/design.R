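#' Block design and boxcar regressors
#'
#' Builds an on/off block design sampled at the TR. With the defaults
#' (TR 2 s, 16 s blocks, 10.5 cycles, starting with stimulus) the run lasts
#' 336 s = 168 time points and both begins and ends on a stimulus block
#' (21 blocks: 11 on, 10 off). For interleaved multi-condition designs an
#' explicit per-block label sequence can be given.
#'
#' @param TR repetition time (s), default 2. Must divide `block_s`.
#' @param block_s block duration (s), default 16.
#' @param cycles number of on/off cycles, default 10.5 (half cycles allowed).
#' @param conditions character vector of stimulus condition names. With one
#'   condition, blocks alternate condition/rest; with several, stimulus
#'   blocks cycle through the conditions in order (each followed by rest).
#' @param block_labels optional explicit per-block label vector (use "rest"
#'   for off blocks); overrides the automatic sequence. Total duration must
#'   equal `cycles * 2 * block_s`.
#' @param start_with_stimulus does the run open with a stimulus block?
#' @return Object of class `block_design`: list with `TR`, `block_s`,
#'   `cycles`, `n_time`, `block_labels`, `conditions`, `boxcars` (an
#'   `n_time x n_conditions` 0/1 matrix) and `frame_times` (s).
#' @export
make_block_design <- function(TR = 2, block_s = 16, cycles = 10.5,
                              conditions = "stim", block_labels = NULL,
                              start_with_stimulus = TRUE) {
  per <- block_s / TR
  if (abs(per - round(per)) > 1e-9)
    stop("TR must divide the block length (non-integer samples per block)")
  per <- round(per)
  total_s <- cycles * 2 * block_s
  n_blocks <- total_s / block_s
  if (abs(n_blocks - round(n_blocks)) > 1e-9)
    stop("cycles must yield a whole number of blocks")
  n_blocks <- round(n_blocks)
  if (is.null(block_labels)) {
    nc <- length(conditions)
    lab <- character(n_blocks)
    ci <- 0L
    for (b in seq_len(n_blocks)) {
      stim_slot <- if (start_with_stimulus) b %% 2 == 1 else b %% 2 == 0
      if (stim_slot) {
        lab[b] <- conditions[ci %% nc + 1L]
        ci <- ci + 1L
      } else lab[b] <- "rest"
    }
    block_labels <- lab
  } else {
    if (length(block_labels) != n_blocks)
      stop("block_labels must have one entry per ", n_blocks, " blocks")
    conditions <- setdiff(unique(block_labels), "rest")
  }
  n_time <- as.integer(n_blocks * per)
  box <- vapply(conditions, function(cc)
    rep(as.numeric(block_labels == cc), each = per), numeric(n_time))
  box <- matrix(box, n_time, length(conditions),
                dimnames = list(NULL, conditions))
  structure(list(TR = TR, block_s = block_s, cycles = cycles,
                 n_time = n_time, samples_per_block = per,
                 block_labels = block_labels, conditions = conditions,
                 boxcars = box,
                 frame_times = (seq_len(n_time) - 1) * TR),
            class = "block_design")
}

#' Canonical double-gamma HRF parameters
#'
#' The standard parameter set: response peak delay 6 s, undershoot delay
#' 16 s, unit dispersions, response:undershoot ratio 6, 32 s kernel.
#'
#' @param peak_delay,undershoot_delay gamma delays (s).
#' @param peak_disp,undershoot_disp gamma dispersions (scale, s).
#' @param ratio response:undershoot amplitude ratio.
#' @param length_s kernel length (s).
#' @return list of class `hrf_params`.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_disp = 1, undershoot_disp = 1,
                       ratio = 6, length_s = 32) {
  stopifnot(peak_delay > 0, undershoot_delay > 0, peak_disp > 0,
            undershoot_disp > 0, ratio > 0, length_s >= undershoot_delay)
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_disp = peak_disp, undershoot_disp = undershoot_disp,
                 ratio = ratio, length_s = length_s), class = "hrf_params")
}

#' Canonical hemodynamic response kernel
#'
#' Difference of two gamma densities (response peak minus ratio-scaled
#' undershoot), sampled at the TR from 0 to the kernel length inclusive and
#' normalized to unit sum. With the defaults the response gamma has shape
#' `peak_delay / peak_disp` = 6 and scale 1, peaking at 5 s.
#'
#' @param TR sampling interval (s).
#' @param params an [hrf_params()].
#' @return numeric kernel (length `length_s / TR + 1`), sums to 1.
#' @export
canonical_hrf <- function(TR = 2, params = hrf_params()) {
  t <- seq(0, params$length_s, by = TR)
  h <- stats::dgamma(t, shape = params$peak_delay / params$peak_disp,
                     scale = params$peak_disp) -
    stats::dgamma(t, shape = params$undershoot_delay / params$undershoot_disp,
                  scale = params$undershoot_disp) / params$ratio
  h / sum(h)
}

#' Convolve design boxcars with an HRF kernel
#'
#' Causal convolution truncated to the design length.
#' @param design a [make_block_design()].
#' @param hrf kernel from [canonical_hrf()] (sampled at the design TR).
#' @return `n_time x n_conditions` matrix of regressors.
#' @export
convolve_design <- function(design, hrf = canonical_hrf(design$TR)) {
  apply(design$boxcars, 2, function(b)
    causal_convolve(b, hrf))
}

causal_convolve <- function(x, k) {
  n <- length(x)
  stats::convolve(x, rev(k), type = "open")[seq_len(n)]
}
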