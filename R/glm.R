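#' High-pass filter by harmonic drift projection
#'
#' Removes slow drift by projecting out paired sine/cosine harmonics at
#' integer frequencies strictly below the cutoff (in cycles per scan),
#' excluding DC; the temporal mean is retained so percent-signal scaling is
#' unaffected. For the 336 s runs modelled here the default cutoff of
#' 4 cycles/scan is 0.0119 Hz. On the discrete grid this removes in-band
#' sinusoids exactly and passes components at or above the cutoff untouched.
#'
#' @param ts numeric time series (or a matrix, one series per column).
#' @param cutoff_cycles_per_scan drift cutoff, default 4.
#' @return filtered series, same shape as `ts`.
#' @export
highpass_filter <- function(ts, cutoff_cycles_per_scan = 4) {
  m <- as.matrix(ts)
  n <- nrow(m)
  if (n < 2 * cutoff_cycles_per_scan)
    stop("series too short for the requested cutoff")
  if (cutoff_cycles_per_scan >= n / 2)
    stop("cutoff at or above the Nyquist frequency")
  kmax <- ceiling(cutoff_cycles_per_scan) - 1
  if (kmax < 1) return(ts)
  t0 <- seq_len(n) - 1
  B <- do.call(cbind, lapply(seq_len(kmax), function(k)
    cbind(cos(2 * pi * k * t0 / n), sin(2 * pi * k * t0 / n))))
  mu <- colMeans(m)
  cen <- sweep(m, 2, mu)
  res <- cen - B %*% qr.solve(crossprod(B), crossprod(B, cen))
  out <- sweep(res, 2, mu, `+`)
  if (is.matrix(ts)) out else drop(out)
}

#' Least-squares BOLD amplitude estimation
#'
#' Ordinary least squares of a (filtered) time series on HRF-convolved
#' regressors plus an intercept. The modulation amplitude is reported in
#' percent signal change, `100 * beta / baseline`, where the baseline is the
#' fitted intercept; its standard error comes from the residual variance and
#' the design covariance.
#'
#' @param ts numeric time series.
#' @param regressors numeric vector or `n x p` matrix of regressors (no
#'   intercept column).
#' @return Object of class `glm_result`: data frame with one row per
#'   regressor (`condition`, `amplitude`, `se`) and attributes `baseline`,
#'   `resid_var`, `beta`, `df_resid`.
#' @export
fit_glm <- function(ts, regressors) {
  y <- as.numeric(ts)
  X <- cbind(`(baseline)` = 1, as.matrix(regressors))
  if (is.null(colnames(X)) || any(colnames(X)[-1] == ""))
    colnames(X) <- c("(baseline)", paste0("cond", seq_len(ncol(X) - 1)))
  if (nrow(X) != length(y)) stop("regressors and series lengths differ")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient design matrix")
  beta <- qr.coef(qx, y)
  res <- y - X %*% beta
  dfr <- length(y) - ncol(X)
  s2 <- sum(res^2) / max(dfr, 1)
  covb <- s2 * chol2inv(qr.R(qx))
  b0 <- beta[1]
  amp <- 100 * beta[-1] / b0
  se <- 100 * sqrt(diag(covb))[-1] / abs(b0)
  out <- data.frame(condition = colnames(X)[-1], amplitude = amp, se = se,
                    row.names = NULL)
  attr(out, "baseline") <- unname(b0)
  attr(out, "resid_var") <- s2
  attr(out, "beta") <- beta
  attr(out, "df_resid") <- dfr
  class(out) <- c("glm_result", class(out))
  out
}

#' Block-permutation significance of the BOLD modulation
#'
#' The observed modulation (absolute regression slope against the
#' HRF-convolved block regressor) is compared with a null distribution built
#' by uniformly permuting the condition labels of whole blocks — preserving
#' the within-block temporal structure of the design — rebuilding the
#' regressor, and refitting. The identity permutation is excluded from the
#' null draws and the plus-one estimator is used, so the smallest attainable
#' p with `nperm` permutations is `1 / (nperm + 1)`. Relabeling at the level
#' of single time points (which destroys the autocorrelation the block
#' design imposes) is available behind `unit = "timepoint"` for comparison
#' only.
#'
#' @param ts filtered time series.
#' @param design a [make_block_design()] (single stimulus condition).
#' @param nperm number of permutations, default 1000.
#' @param seed integer seed.
#' @param hrf an [hrf_params()].
#' @param unit `"block"` (default) or `"timepoint"`.
#' @return p-value in (0, 1]; attributes `observed` (the |slope|), `nperm`,
#'   and `with_replacement` (TRUE when fewer distinct relabelings than
#'   `nperm` exist, in which case sampling is with replacement).
#' @export
permutation_pvalue <- function(ts, design, nperm = 1000, seed = 1L,
                               hrf = hrf_params(), unit = c("block",
                                                            "timepoint")) {
  unit <- match.arg(unit)
  stopifnot(nperm >= 1)
  y <- as.numeric(ts)
  kern <- canonical_hrf(design$TR, hrf)
  x_obs <- causal_convolve(design$boxcars[, 1], kern)
  obs <- abs(slope_only(x_obs, y))

  labs <- design$boxcars[, 1] > 0          # per-TR on/off
  blab <- design$block_labels == design$conditions[1]
  n_blocks <- length(blab)
  n_distinct <- choose(n_blocks, sum(blab)) - 1   # excluding identity
  with_repl <- n_distinct < nperm && unit == "block"

  rng <- local_rng(seed)
  per <- design$samples_per_block
  null_amp <- numeric(nperm)
  B <- matrix(0, design$n_time, nperm)
  for (p in seq_len(nperm)) {
    repeat {
      if (unit == "block") {
        pb <- rng$sample(blab)
        if (!all(pb == blab)) break        # identity excluded
        if (n_distinct < 1) break          # degenerate design: accept
      } else {
        pb <- NULL
        break
      }
    }
    B[, p] <- if (unit == "block") rep(as.numeric(pb), each = per)
    else as.numeric(rng$sample(labs))
  }
  # convolve all permuted boxcars at once, then vectorized slopes
  ncB <- ncol(B)
  Rg <- apply(B, 2, causal_convolve, k = kern)
  xc <- sweep(Rg, 2, colMeans(Rg))
  yc <- y - mean(y)
  null_amp <- abs(colSums(xc * yc) / colSums(xc^2))
  pval <- (1 + sum(null_amp >= obs)) / (nperm + 1)
  attr(pval, "observed") <- obs
  attr(pval, "nperm") <- nperm
  attr(pval, "with_replacement") <- with_repl
  pval
}

slope_only <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sum(xc^2)
}

# vectorized permutation p-values for many voxels sharing one design and one
# null permutation set (standard for voxel-wise maps)
perm_pvalues_matrix <- function(Y, design, nperm = 1000, seed = 1L,
                                hrf = hrf_params()) {
  kern <- canonical_hrf(design$TR, hrf)
  x_obs <- causal_convolve(design$boxcars[, 1], kern)
  xo <- x_obs - mean(x_obs)
  Yc <- sweep(Y, 2, colMeans(Y))           # Y: n_time x n_vox
  obs <- abs(colSums(xo * Yc) / sum(xo^2))

  blab <- design$block_labels == design$conditions[1]
  per <- design$samples_per_block
  rng <- local_rng(seed)
  exceed <- numeric(ncol(Y))
  for (p in seq_len(nperm)) {
    repeat {
      pb <- rng$sample(blab)
      if (!all(pb == blab)) break
    }
    x <- causal_convolve(rep(as.numeric(pb), each = per), kern)
    xc <- x - mean(x)
    amp <- abs(colSums(xc * Yc) / sum(xc^2))
    exceed <- exceed + (amp >= obs)
  }
  (1 + exceed) / (nperm + 1)
}

#' Response latency from the stimulus-frequency Fourier phase
#'
#' Phase of the discrete Fourier component at the block-alternation
#' frequency (`n_cycles` per scan), with the sign convention that a pure
#' delayed response `cos(2 pi n_cycles t / T - phi)` maps to latency
#' `phi * cycle_s / (2 pi)`; the phase is wrapped to a latency in
#' `[0, cycle_s)` (0-32 s for the 32 s cycle).
#'
#' @param ts time series covering an integer number of cycles at the target
#'   frequency (the half-cycle of a 10.5-cycle run contributes negligibly).
#' @param n_cycles stimulus cycles per scan, default 10.
#' @param cycle_s cycle duration (s), default 32.
#' @return latency in seconds; attribute `power` (squared magnitude of the
#'   component).
#' @export
fourier_latency <- function(ts, n_cycles = 10, cycle_s = 32) {
  y <- as.numeric(ts)
  n <- length(y)
  if (n < n_cycles) stop("series shorter than the requested cycle count")
  co <- sum(y * exp(-2i * pi * n_cycles * (seq_len(n) - 1) / n))
  pw <- Mod(co)^2
  if (pw < (n * .Machine$double.eps * max(1, mean(abs(y))))^2)
    stop("no power at the stimulus frequency: latency undefined")
  phi <- (-Arg(co)) %% (2 * pi)
  lat <- phi * cycle_s / (2 * pi)
  attr(lat, "power") <- pw
  lat
}
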