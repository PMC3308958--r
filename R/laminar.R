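#' Equally populated depth bins
#'
#' Voxels are stably sorted by relative depth (ties broken by their input
#' order) and split into `k` contiguous groups whose sizes differ by at most
#' one, the deeper bins (nearest the WM surface) taking the remainder.
#'
#' @param rel_depth numeric vector of relative depths.
#' @param k number of bins, default 5.
#' @return integer bin assignment (1 = deepest) aligned with `rel_depth`.
#' @export
bin_by_depth <- function(rel_depth, k = 5) {
  n <- length(rel_depth)
  if (n < k) stop("fewer voxels than bins")
  ord <- order(rel_depth)                    # stable: ties keep input order
  base <- n %/% k; extra <- n %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  bins <- integer(n)
  bins[ord] <- rep(seq_len(k), times = sizes)
  bins
}

#' Laminar response profile of an ROI
#'
#' Implements average-then-regress: within each of `k` equally populated
#' depth bins the voxel time series are averaged first, the averaged series
#' is high-pass filtered, and the per-condition response amplitude and
#' standard error are estimated by [fit_glm()] on that single series. A WM
#' reference amplitude is computed identically from the ROI's adjacent WM
#' voxels (one face-adjacent shell into white matter); if that set is empty
#' the reference is reported as missing.
#'
#' @param session a [simulate_session()] (or any object with `data`,
#'   `tissue`, `design` of the same classes).
#' @param depth data frame with voxel grid indices `i,j,k` and `rel_depth`
#'   (a `depth_map` or `depth_truth`).
#' @param roi integer linear voxel indices of the ROI (GM voxels), or NULL
#'   to use every voxel of `depth` with a finite depth.
#' @param k number of depth bins, default 5.
#' @param hrf an [hrf_params()].
#' @param cutoff high-pass cutoff (cycles/scan), default 4.
#' @return Object of class `laminar_profile`: data frame with one row per
#'   bin x condition (`bin`, `mean_depth`, `n_voxels`, `condition`,
#'   `amplitude`, `se`) with WM reference rows as `bin = 0`
#'   (`mean_depth = NA`); attribute `k`.
#' @export
laminar_profile <- function(session, depth, roi = NULL, k = 5,
                            hrf = hrf_params(), cutoff = 4) {
  tissue <- session$tissue
  dep <- depth[!is.na(depth$rel_depth), , drop = FALSE]
  lin <- voxel_linear_index(tissue, dep$i, dep$j, dep$k)
  if (!is.null(roi)) {
    keep <- lin %in% roi
    dep <- dep[keep, , drop = FALSE]
    lin <- lin[keep]
  }
  if (nrow(dep) < k) stop("ROI has fewer depth-labeled voxels than bins")
  bins <- bin_by_depth(dep$rel_depth, k)
  design <- session$design
  kern_reg <- convolve_design(design, canonical_hrf(design$TR, hrf))
  # drift projection is applied to data and regressors alike, so in-band
  # leakage of the block regressor does not bias the amplitude
  kern_reg <- apply(kern_reg, 2, highpass_filter,
                    cutoff_cycles_per_scan = cutoff)
  Y <- voxel_timeseries(session, lin)      # n_time x n_vox

  fit_one <- function(cols) {
    ts <- rowMeans(Y[, cols, drop = FALSE])
    fit_glm(highpass_filter(ts, cutoff), kern_reg)
  }
  rows <- lapply(seq_len(k), function(b) {
    cols <- which(bins == b)
    g <- fit_one(cols)
    data.frame(bin = b, mean_depth = mean(dep$rel_depth[cols]),
               n_voxels = length(cols), condition = g$condition,
               amplitude = g$amplitude, se = g$se)
  })
  out <- do.call(rbind, rows)

  wm_lin <- wm_adjacent_voxels(tissue, lin)
  if (length(wm_lin)) {
    Yw <- voxel_timeseries(session, wm_lin)
    gw <- fit_glm(highpass_filter(rowMeans(Yw), cutoff), kern_reg)
    out <- rbind(data.frame(bin = 0, mean_depth = NA_real_,
                            n_voxels = length(wm_lin),
                            condition = gw$condition,
                            amplitude = gw$amplitude, se = gw$se), out)
  }
  attr(out, "k") <- k
  attr(out, "wm_reference_missing") <- length(wm_lin) == 0
  class(out) <- c("laminar_profile", class(out))
  out
}

voxel_timeseries <- function(session, lin) {
  d <- session$tissue$dims
  n_t <- dim(session$data)[4]
  m <- matrix(session$data, prod(d), n_t)
  t(m[lin, , drop = FALSE])
}

# one face-adjacent shell of WM voxels around an ROI
wm_adjacent_voxels <- function(tissue, roi_lin) {
  d <- tissue$dims
  idx <- arrayInd(roi_lin, d)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  nb <- do.call(rbind, lapply(seq_len(6), function(o)
    sweep(idx, 2, offs[o, ], `+`)))
  ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
    nb[, 3] >= 1 & nb[, 3] <= d[3]
  nb <- nb[ok, , drop = FALSE]
  lin <- unique(voxel_linear_index(tissue, nb[, 1], nb[, 2], nb[, 3]))
  lin <- setdiff(lin, roi_lin)
  lin[as.vector(tissue$labels)[lin] == 1L]
}

#' Face-connected components of a voxel mask
#'
#' @param mask logical 3D array.
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(mask) {
  d <- dim(mask)
  lin <- which(mask)
  lab <- array(0L, d)
  if (!length(lin)) return(lab)
  idx <- arrayInd(lin, d)
  pos <- integer(prod(d)); pos[lin] <- seq_along(lin)
  edges <- NULL
  for (ax in 1:3) {
    nb <- idx
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= d[ax]
    nlin <- (nb[ok, 3] - 1L) * d[1] * d[2] + (nb[ok, 2] - 1L) * d[1] + nb[ok, 1]
    hit <- pos[nlin] > 0
    edges <- rbind(edges, cbind(which(ok)[hit], pos[nlin[hit]]))
  }
  if (is.null(edges) || nrow(edges) == 0) {
    lab[lin] <- seq_along(lin)
    return(lab)
  }
  g <- igraph::graph_from_edgelist(edges[, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(lin) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[lin] <- as.integer(comp)
  lab
}

#' Detect clusters of activated voxels
#'
#' Each volume of the session is smoothed with an isotropic Gaussian
#' (sigma 1.4 mm by default, for region-of-interest definition only), the
#' per-voxel modulation amplitude and block-permutation p-value are
#' recomputed on the smoothed data, and face-connected components of
#' voxels with `p < p_thresh` (default 0.001, uncorrected) of at least
#' `min_voxels` (default 100) voxels are returned. Profile estimation must
#' reuse the unsmoothed data; this function only defines the ROIs. Each
#' cluster is dilated through the full cortical depth (all GM voxels of the
#' grid columns it touches are included via the depth map) and tagged with
#' the majority retinotopic label of its voxels.
#'
#' @param session a [simulate_session()].
#' @param depth depth data frame with retinotopic tags (`depth_truth`) or
#'   NULL.
#' @param sigma_mm smoothing sigma (mm), default 1.4.
#' @param p_thresh uncorrected p threshold on the smoothed data.
#' @param min_voxels minimum cluster extent, default 100.
#' @param nperm,seed permutation parameters ([perm_pvalues_matrix] shares
#'   one null permutation set across voxels).
#' @param gm_only restrict suprathreshold voxels to GM (default TRUE).
#' @return list of `cluster_roi` objects: `voxels` (linear indices),
#'   `wm_adjacent`, `size`, `ecc_band`, `polar_wedge`, `amplitude_map`
#'   mean.
#' @export
detect_clusters <- function(session, depth = NULL, sigma_mm = 1.4,
                            p_thresh = 0.001, min_voxels = 100,
                            nperm = 1000, seed = 1L, gm_only = TRUE) {
  tissue <- session$tissue
  d <- tissue$dims
  n_t <- dim(session$data)[4]
  sm <- session$data
  sig_vox <- sigma_mm / tissue$voxel
  kk <- gauss_kernel_1d(sig_vox)
  for (t in seq_len(n_t))
    sm[, , , t] <- gaussian_blur_3d(sm[, , , t, drop = FALSE][, , , 1], kk)

  Y <- matrix(sm, prod(d), n_t)
  cand <- if (gm_only) which(as.vector(tissue$labels) == 2L)
  else seq_len(prod(d))
  Yc <- highpass_filter(t(Y[cand, , drop = FALSE]))
  pv <- perm_pvalues_matrix(Yc, session$design, nperm = nperm, seed = seed)

  mask <- array(FALSE, d)
  mask[cand[pv < p_thresh]] <- TRUE
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_voxels)
  lapply(keep, function(cl) {
    lin <- which(lab == cl)
    if (!is.null(depth)) {
      dl <- voxel_linear_index(tissue, depth$i, depth$j, depth$k)
      cols_roi <- unique((arrayInd(lin, d)[, 1] - 1) + d[1] *
                           (arrayInd(lin, d)[, 2] - 1))
      cols_all <- (depth$i - 1) + d[1] * (depth$j - 1)
      lin <- sort(unique(c(lin, dl[cols_all %in% cols_roi])))
    }
    tag <- c(ecc_band = NA_integer_, polar_wedge = NA_integer_)
    if (!is.null(depth) && all(c("ecc_band", "polar_wedge") %in% names(depth))) {
      dl <- voxel_linear_index(tissue, depth$i, depth$j, depth$k)
      sel <- match(lin, dl)
      sel <- sel[!is.na(sel)]
      if (length(sel)) {
        tag["ecc_band"] <- majority(depth$ecc_band[sel])
        tag["polar_wedge"] <- majority(depth$polar_wedge[sel])
      }
    }
    structure(list(voxels = lin,
                   wm_adjacent = wm_adjacent_voxels(tissue, lin),
                   size = length(lin), ecc_band = tag[["ecc_band"]],
                   polar_wedge = tag[["polar_wedge"]]),
              class = "cluster_roi")
  })
}

majority <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_integer_)
  as.integer(names(sort(table(x), decreasing = TRUE))[1])
}

#' ROI eligibility rules
#'
#' An ROI is excluded when (i) its WM reference amplitudes for the two
#' conditions differ by more than `max(wm_delta_pct, 2 * mean_se)` — the WM
#' baseline-stability rule, with 0.16% being twice the average amplitude
#' standard error in the data this models; (ii) any depth bin holds fewer
#' than `min_bin_voxels` (40) voxels; or (iii) the fraction of time a
#' stimulus was present at the ROI's visual-field location is below
#' `min_presence` (0.25).
#'
#' @param profile a [laminar_profile()] with two conditions and WM rows.
#' @param presence_fraction stimulus-presence fraction at the ROI's
#'   retinotopic location.
#' @param wm_delta_pct constant WM-stability threshold (percent signal),
#'   default 0.16.
#' @param mean_se average amplitude standard error across ROIs (percent
#'   signal); the effective threshold is `max(wm_delta_pct, 2 * mean_se)`.
#'   NULL uses the constant alone.
#' @param min_bin_voxels minimum voxels per bin, default 40.
#' @param min_presence minimum stimulus-presence fraction, default 0.25.
#' @return list of class `roi_eligibility`: flags `wm_stable`,
#'   `bins_populated`, `stimulus_present`, overall `eligible`,
#'   the `wm_delta` observed and `wm_threshold` applied, and the
#'   depth-averaged `condition_preference`.
#' @export
roi_eligibility <- function(profile, presence_fraction,
                            wm_delta_pct = 0.16, mean_se = NULL,
                            min_bin_voxels = 40, min_presence = 0.25) {
  conds <- unique(profile$condition)
  if (length(conds) != 2) stop("eligibility rules need exactly two conditions")
  wm <- profile[profile$bin == 0, ]
  if (nrow(wm) == 2) {
    wm_delta <- abs(wm$amplitude[wm$condition == conds[1]] -
                      wm$amplitude[wm$condition == conds[2]])
  } else wm_delta <- NA_real_     # missing WM reference: degrade gracefully
  thr <- max(wm_delta_pct, if (is.null(mean_se)) 0 else 2 * mean_se)
  wm_stable <- if (is.na(wm_delta)) NA else wm_delta <= thr
  gm <- profile[profile$bin > 0, ]
  bins_pop <- all(tapply(gm$n_voxels, gm$bin, max) >= min_bin_voxels)
  present <- presence_fraction >= min_presence
  pref <- {
    m <- tapply(gm$amplitude, gm$condition, mean)
    names(which.max(m))
  }
  structure(list(wm_stable = wm_stable, bins_populated = bins_pop,
                 stimulus_present = present,
                 eligible = isTRUE(wm_stable) && bins_pop && present,
                 wm_delta = wm_delta, wm_threshold = thr,
                 condition_preference = pref),
            class = "roi_eligibility")
}

#' Differential laminar profile
#'
#' Per depth bin, the amplitude difference `cond_a - cond_b` with standard
#' errors combined in quadrature. Antisymmetric under condition swap.
#'
#' @param profile a [laminar_profile()] containing both conditions.
#' @param cond_a,cond_b condition names; by default the first two in the
#'   profile (`cond_a - cond_b`).
#' @return data frame `bin`, `mean_depth`, `diff`, `se` (GM bins only).
#' @export
differential_profile <- function(profile, cond_a = NULL, cond_b = NULL) {
  gm <- profile[profile$bin > 0, ]
  conds <- unique(gm$condition)
  if (is.null(cond_a)) cond_a <- conds[1]
  if (is.null(cond_b)) cond_b <- conds[2]
  if (!all(c(cond_a, cond_b) %in% conds))
    stop("profile is missing a requested condition")
  a <- gm[gm$condition == cond_a, ]
  b <- gm[gm$condition == cond_b, ]
  a <- a[order(a$bin), ]; b <- b[order(b$bin), ]
  data.frame(bin = a$bin, mean_depth = a$mean_depth,
             diff = a$amplitude - b$amplitude,
             se = sqrt(a$se^2 + b$se^2))
}

#' One-way depth ANOVA across ROIs
#'
#' Fixed-effects ANOVA with depth bin as the factor and ROIs (or subjects)
#' as independent replicates: `df = (k - 1, r * k - k)`, reproducing, e.g.,
#' (4, 30) for 7 ROIs x 5 bins and (4, 10) for 3 ROIs x 5 bins.
#'
#' @param values numeric `r x k` matrix (rows = ROIs, columns = depth bins).
#' @return list of class `anova_result`: `F`, `df1`, `df2`, `p`.
#' @export
depth_anova <- function(values) {
  values <- as.matrix(values)
  r <- nrow(values); k <- ncol(values)
  if (r < 2) stop("depth ANOVA needs at least 2 replicates (ROIs)")
  df <- data.frame(y = as.vector(values),
                   bin = factor(rep(seq_len(k), each = r)))
  a <- stats::anova(stats::lm(y ~ bin, data = df))
  structure(list(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
                 p = a$`Pr(>F)`[1]), class = "anova_result")
}

#' Per-depth paired t-tests with Bonferroni correction
#'
#' Two-sided paired t-test in each depth bin, Bonferroni-corrected for
#' `n_comparisons` (twice the bin count by default: 10 comparisons for the
#' 5-bin analysis). Significance is flagged at corrected 0.05 and 0.1.
#'
#' @param a,b numeric `n x k` matrices of paired per-bin amplitudes
#'   (rows = subjects/ROIs).
#' @param n_comparisons correction factor, default `2 * k`.
#' @return data frame per bin: `t`, `p`, `p_corrected`, `sig05`, `sig10`.
#' @export
paired_t_by_depth <- function(a, b, n_comparisons = 2 * ncol(as.matrix(a))) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)))
  if (nrow(a) < 2) stop("paired t-test needs at least 2 pairs")
  k <- ncol(a)
  res <- lapply(seq_len(k), function(bn) {
    d <- a[, bn] - b[, bn]
    if (stats::sd(d) == 0) {
      # degenerate pairs: identical -> no evidence; constant offset ->
      # infinitely strong evidence
      if (mean(d) == 0) data.frame(bin = bn, t = 0, p = 1)
      else data.frame(bin = bn, t = sign(mean(d)) * Inf, p = 0)
    } else {
      tt <- stats::t.test(a[, bn], b[, bn], paired = TRUE)
      data.frame(bin = bn, t = unname(tt$statistic), p = tt$p.value)
    }
  })
  out <- do.call(rbind, res)
  out$p_corrected <- pmin(1, out$p * n_comparisons)
  out$sig05 <- out$p_corrected < 0.05
  out$sig10 <- out$p_corrected < 0.1
  out
}

#' Latency as a function of cortical depth
#'
#' Per subject, all scans are averaged, voxels are divided into `k` equally
#' populated depth bins, each bin-averaged (and high-pass filtered) series
#' is reduced to a latency via [fourier_latency()], and the subject's mean
#' latency is subtracted. A depth ANOVA across subjects tests the main
#' effect of depth on latency.
#'
#' @param sessions list of subjects; each element is a single
#'   [simulate_session()] or a list of repeated sessions to average.
#' @param depth depth data frame (shared grid across subjects).
#' @param roi linear voxel indices or NULL.
#' @param k bins, default 5.
#' @param n_cycles,cycle_s Fourier component, defaults 10 cycles of 32 s.
#' @param cutoff high-pass cutoff (cycles/scan).
#' @return list: `latency` (subjects x k matrix of mean-subtracted
#'   latencies, s), `raw` (before mean subtraction), `anova`
#'   (an `anova_result`), `mean_depth` per bin.
#' @export
latency_by_depth <- function(sessions, depth, roi = NULL, k = 5,
                             n_cycles = 10, cycle_s = 32, cutoff = 4) {
  one_subject <- function(subj) {
    runs <- if (inherits(subj, "simulated_session")) list(subj) else subj
    tissue <- runs[[1]]$tissue
    dep <- depth[!is.na(depth$rel_depth), , drop = FALSE]
    lin <- voxel_linear_index(tissue, dep$i, dep$j, dep$k)
    if (!is.null(roi)) {
      keepv <- lin %in% roi
      dep <- dep[keepv, , drop = FALSE]; lin <- lin[keepv]
    }
    bins <- bin_by_depth(dep$rel_depth, k)
    Ys <- lapply(runs, voxel_timeseries, lin = lin)
    Y <- Reduce(`+`, Ys) / length(Ys)
    lat <- vapply(seq_len(k), function(b) {
      ts <- rowMeans(Y[, bins == b, drop = FALSE])
      as.numeric(fourier_latency(highpass_filter(ts, cutoff),
                                 n_cycles, cycle_s))
    }, numeric(1))
    list(lat = lat,
         mean_depth = tapply(dep$rel_depth, bins, mean))
  }
  per <- lapply(sessions, one_subject)
  raw <- do.call(rbind, lapply(per, `[[`, "lat"))
  centered <- sweep(raw, 1, rowMeans(raw))
  list(latency = centered, raw = raw,
       anova = if (nrow(centered) >= 2) depth_anova(centered) else NULL,
       mean_depth = per[[1]]$mean_depth)
}
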