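#' Cortical depth from matched WM/GM vertex segments
#'
#' The paper's default metric. Every segment joining matched WM and GM
#' vertices is intersected with the voxel grid (exact segment/axis-aligned
#' cube intersection: a voxel is "traversed" if the segment enters its cube,
#' not merely passes near its center). A traversed GM voxel's absolute depth
#' is the mean, over traversing segments, of the scalar projection of
#' (voxel center - WM endpoint) onto the unit segment direction, clamped to
#' the segment; its local thickness is the mean traversing-segment length;
#' relative depth is their ratio, clipped to 0-1. GM voxels traversed by no
#' segment are left unlabeled (NA).
#'
#' @param pair a [surface_pair()].
#' @param tissue a `tissue_volume` from [voxelize()].
#' @return A `depth_map` data frame, one row per GM voxel: grid indices,
#'   world coordinates, `abs_depth` (mm), `thickness` (mm), `rel_depth`,
#'   `n_segments`, `len_cv` (coefficient of variation of traversing segment
#'   lengths, flagging voxels reached from both banks of a sulcus),
#'   `qc_pass` (set by [qc_filter()], initially NA), with attributes
#'   `metric` and `skipped_segments`.
#' @export
matched_faces_depth <- function(pair, tissue) {
  seg <- list(p0 = pair$wm$vertices, p1 = pair$gm$vertices, skipped = 0L)
  segments_to_depthmap(seg, tissue, metric = "matched_faces")
}

#' Cortical depth along WM-surface normals / shortest WM-to-GM lines
#'
#' Same contract as [matched_faces_depth()] but with segments defined by
#' (`wm_normal_depth`) WM vertex normals extended until they intersect the
#' GM surface, or (`nearest_gm_depth`) the shortest line from each WM vertex
#' to the GM surface. Normals that fail to intersect the GM surface within
#' 3x the median matched-vertex thickness are skipped and counted in the
#' `skipped_segments` attribute.
#'
#' @inheritParams matched_faces_depth
#' @return A `depth_map` data frame (see [matched_faces_depth()]).
#' @export
wm_normal_depth <- function(pair, tissue) {
  nrm <- vertex_normals(pair$wm)
  med_th <- stats::median(sqrt(rowSums((pair$gm$vertices - pair$wm$vertices)^2)))
  hits <- ray_mesh_intersect(pair$wm$vertices, nrm, pair$gm,
                             max_dist = 3 * med_th)
  ok <- is.finite(hits)
  seg <- list(p0 = pair$wm$vertices[ok, , drop = FALSE],
              p1 = pair$wm$vertices[ok, , drop = FALSE] +
                nrm[ok, , drop = FALSE] * hits[ok],
              skipped = sum(!ok))
  segments_to_depthmap(seg, tissue, metric = "wm_normal")
}

#' @rdname wm_normal_depth
#' @export
nearest_gm_depth <- function(pair, tissue) {
  med_th <- stats::median(sqrt(rowSums((pair$gm$vertices - pair$wm$vertices)^2)))
  cp <- closest_point_on_mesh(pair$wm$vertices, pair$gm,
                              search_radius = 3 * med_th)
  ok <- is.finite(cp[, 1])
  seg <- list(p0 = pair$wm$vertices[ok, , drop = FALSE],
              p1 = cp[ok, , drop = FALSE],
              skipped = sum(!ok))
  segments_to_depthmap(seg, tissue, metric = "nearest_gm")
}

# ---- segment machinery -----------------------------------------------------

# accumulate per-voxel depth/thickness over all segments
segments_to_depthmap <- function(seg, tissue, metric) {
  p0 <- seg$p0; p1 <- seg$p1
  if (!nrow(p0)) stop("no usable segments")
  d <- tissue$dims; vox <- tissue$voxel; org <- tissue$origin
  nvox <- prod(d)
  sum_depth <- numeric(nvox); sum_len <- numeric(nvox)
  sum_len2 <- numeric(nvox); n_seg <- integer(nvox)

  u <- p1 - p0
  L <- sqrt(rowSums(u^2))
  uhat <- u / L
  for (s in seq_len(nrow(p0))) {
    hit <- segment_voxel_hits(p0[s, ], p1[s, ], d, vox, org)
    if (!length(hit$lin)) next
    dep <- pmin(pmax((hit$centers - matrix(p0[s, ], nrow(hit$centers), 3,
                                           byrow = TRUE)) %*% uhat[s, ],
                     0), L[s])
    sum_depth[hit$lin] <- sum_depth[hit$lin] + dep
    sum_len[hit$lin] <- sum_len[hit$lin] + L[s]
    sum_len2[hit$lin] <- sum_len2[hit$lin] + L[s]^2
    n_seg[hit$lin] <- n_seg[hit$lin] + 1L
  }

  gm_lin <- which(as.vector(tissue$labels) == 2L)
  if (!any(n_seg[gm_lin] > 0))
    stop("no segments traverse any GM voxel; refine the surface meshes ",
         "(mesh edge length should not exceed the voxel size)")
  idx <- arrayInd(gm_lin, d)
  ctr <- voxel_centers(tissue, idx[, 1], idx[, 2], idx[, 3])
  n <- n_seg[gm_lin]
  abs_depth <- ifelse(n > 0, sum_depth[gm_lin] / pmax(n, 1), NA_real_)
  thick <- ifelse(n > 0, sum_len[gm_lin] / pmax(n, 1), NA_real_)
  mlen2 <- sum_len2[gm_lin] / pmax(n, 1)
  len_sd <- sqrt(pmax(0, mlen2 - thick^2))
  dm <- data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3],
                   x = ctr[, 1], y = ctr[, 2], z = ctr[, 3],
                   abs_depth = abs_depth, thickness = thick,
                   rel_depth = pmin(pmax(abs_depth / thick, 0), 1),
                   n_segments = n,
                   len_cv = ifelse(n > 1, len_sd / thick, 0),
                   qc_pass = NA)
  attr(dm, "metric") <- metric
  attr(dm, "skipped_segments") <- seg$skipped
  class(dm) <- c("depth_map", class(dm))
  dm
}

# exact segment / axis-aligned voxel-cube intersection (slab clipping),
# vectorized over the candidate voxels in the segment's bounding box
segment_voxel_hits <- function(a, b, dims, vox, org) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  i0 <- pmax(1L, floor((lo - org) / vox - 1e-12) + 1L)
  i1 <- pmin(dims, floor((hi - org) / vox + 1e-12) + 1L)
  if (any(i1 < i0)) return(list(lin = integer(0)))
  g <- expand.grid(i = i0[1]:i1[1], j = i0[2]:i1[2], k = i0[3]:i1[3],
                   KEEP.OUT.ATTRS = FALSE)
  cmin <- cbind(org[1] + (g$i - 1) * vox, org[2] + (g$j - 1) * vox,
                org[3] + (g$k - 1) * vox)
  cmax <- cmin + vox
  dvec <- b - a
  t0 <- rep(0, nrow(g)); t1 <- rep(1, nrow(g))
  for (ax in 1:3) {
    if (abs(dvec[ax]) < 1e-14) {
      miss <- a[ax] < cmin[, ax] - 1e-12 | a[ax] > cmax[, ax] + 1e-12
      t1[miss] <- -1    # no overlap in this slab
    } else {
      ta <- (cmin[, ax] - a[ax]) / dvec[ax]
      tb <- (cmax[, ax] - a[ax]) / dvec[ax]
      tlo <- pmin(ta, tb); thi <- pmax(ta, tb)
      t0 <- pmax(t0, tlo); t1 <- pmin(t1, thi)
    }
  }
  hit <- t1 >= t0 - 1e-12
  if (!any(hit)) return(list(lin = integer(0)))
  g <- g[hit, , drop = FALSE]
  lin <- as.integer((g$k - 1L) * dims[1] * dims[2] + (g$j - 1L) * dims[1] + g$i)
  centers <- cbind(org[1] + (g$i - 0.5) * vox, org[2] + (g$j - 0.5) * vox,
                   org[3] + (g$k - 0.5) * vox)
  list(lin = lin, centers = centers)
}

# spatial hash of face bounding spheres for candidate prefiltering
face_grid_hash <- function(mesh, cell) {
  f <- mesh$faces; v <- mesh$vertices
  cen <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
            v[f[, 3], , drop = FALSE]) / 3
  key <- paste(floor(cen[, 1] / cell), floor(cen[, 2] / cell), sep = ",")
  split(seq_len(nrow(f)), key)
}

candidate_faces <- function(hash, p, cell, ring = 1L) {
  cx <- floor(p[1] / cell); cy <- floor(p[2] / cell)
  keys <- as.vector(outer((cx - ring):(cx + ring), (cy - ring):(cy + ring),
                          function(a, b) paste(a, b, sep = ",")))
  unlist(hash[keys], use.names = FALSE)
}

# first intersection distance of rays with a mesh (Moller-Trumbore),
# NA where no hit within max_dist
ray_mesh_intersect <- function(origins, dirs, mesh, max_dist) {
  cell <- max_dist
  hash <- face_grid_hash(mesh, cell)
  v <- mesh$vertices; f <- mesh$faces
  out <- rep(NA_real_, nrow(origins))
  for (s in seq_len(nrow(origins))) {
    cand <- candidate_faces(hash, origins[s, ], cell)
    if (!length(cand)) next
    v0 <- v[f[cand, 1], , drop = FALSE]
    e1 <- v[f[cand, 2], , drop = FALSE] - v0
    e2 <- v[f[cand, 3], , drop = FALSE] - v0
    dir <- dirs[s, ]
    pv <- cbind(dir[2] * e2[, 3] - dir[3] * e2[, 2],
                dir[3] * e2[, 1] - dir[1] * e2[, 3],
                dir[1] * e2[, 2] - dir[2] * e2[, 1])
    det <- rowSums(e1 * pv)
    ok <- abs(det) > 1e-12
    tv <- matrix(origins[s, ], nrow(v0), 3, byrow = TRUE) - v0
    uu <- rowSums(tv * pv) / det
    qv <- cbind(tv[, 2] * e1[, 3] - tv[, 3] * e1[, 2],
                tv[, 3] * e1[, 1] - tv[, 1] * e1[, 3],
                tv[, 1] * e1[, 2] - tv[, 2] * e1[, 1])
    vv <- (qv[, 1] * dir[1] + qv[, 2] * dir[2] + qv[, 3] * dir[3]) / det
    tt <- rowSums(e2 * qv) / det
    ok <- ok & uu >= -1e-9 & vv >= -1e-9 & (uu + vv) <= 1 + 1e-9 &
      tt > 1e-9 & tt <= max_dist
    if (any(ok)) out[s] <- min(tt[ok])
  }
  out
}

# closest point on a mesh from each query point (exact point-triangle
# projection over hashed candidate faces); NA rows where no face within
# the search radius
closest_point_on_mesh <- function(points, mesh, search_radius) {
  cell <- search_radius
  hash <- face_grid_hash(mesh, cell)
  v <- mesh$vertices; f <- mesh$faces
  out <- matrix(NA_real_, nrow(points), 3)
  for (s in seq_len(nrow(points))) {
    cand <- candidate_faces(hash, points[s, ], cell)
    if (!length(cand)) next
    cp <- point_triangle_closest(points[s, ],
                                 v[f[cand, 1], , drop = FALSE],
                                 v[f[cand, 2], , drop = FALSE],
                                 v[f[cand, 3], , drop = FALSE])
    d2 <- rowSums((cp - matrix(points[s, ], nrow(cp), 3, byrow = TRUE))^2)
    best <- which.min(d2)
    if (d2[best] <= search_radius^2) out[s, ] <- cp[best, ]
  }
  out
}

# closest points on triangles (a,b,c) to point p, vectorized over triangles
# (Ericson, Real-Time Collision Detection, 5.1.5)
point_triangle_closest <- function(p, a, b, c) {
  n <- nrow(a)
  P <- matrix(p, n, 3, byrow = TRUE)
  ab <- b - a; ac <- c - a; ap <- P - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- P - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp_ <- P - c
  d5 <- rowSums(ab * cp_); d6 <- rowSums(ac * cp_)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  out <- matrix(NA_real_, n, 3)
  # vertex regions
  m <- d1 <= 0 & d2 <= 0; out[m, ] <- a[m, , drop = FALSE]
  m2 <- is.na(out[, 1]) & d3 >= 0 & d4 <= d3; out[m2, ] <- b[m2, , drop = FALSE]
  m3 <- is.na(out[, 1]) & d6 >= 0 & d5 <= d6; out[m3, ] <- c[m3, , drop = FALSE]
  # edge AB
  m4 <- is.na(out[, 1]) & vc <= 0 & d1 >= 0 & d3 <= 0
  if (any(m4)) {
    w <- d1[m4] / (d1[m4] - d3[m4])
    out[m4, ] <- a[m4, , drop = FALSE] + ab[m4, , drop = FALSE] * w
  }
  # edge AC
  m5 <- is.na(out[, 1]) & vb <= 0 & d2 >= 0 & d6 <= 0
  if (any(m5)) {
    w <- d2[m5] / (d2[m5] - d6[m5])
    out[m5, ] <- a[m5, , drop = FALSE] + ac[m5, , drop = FALSE] * w
  }
  # edge BC
  m6 <- is.na(out[, 1]) & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  if (any(m6)) {
    w <- (d4[m6] - d3[m6]) / ((d4[m6] - d3[m6]) + (d5[m6] - d6[m6]))
    out[m6, ] <- b[m6, , drop = FALSE] +
      (c[m6, , drop = FALSE] - b[m6, , drop = FALSE]) * w
  }
  # interior
  m7 <- is.na(out[, 1])
  if (any(m7)) {
    denom <- va[m7] + vb[m7] + vc[m7]
    vv <- vb[m7] / denom; ww <- vc[m7] / denom
    out[m7, ] <- a[m7, , drop = FALSE] + ab[m7, , drop = FALSE] * vv +
      ac[m7, , drop = FALSE] * ww
  }
  out
}

#' Thickness-based segmentation QC
#'
#' Flags voxels whose local cortical thickness is not strictly below the
#' threshold (the segmentation-quality rule: thickness must be less than
#' 4 mm) and summarizes the map.
#'
#' @param depthmap a `depth_map`.
#' @param max_thickness_mm exclusion threshold (mm), default 4; a voxel at
#'   exactly the threshold fails (strict "less than").
#' @param len_cv_max dispersion flag: voxels whose traversing-segment
#'   lengths vary by more than this fraction of their mean (default 0.5,
#'   e.g. segments arriving from both banks of a sulcus) are reported in
#'   the QC summary (not excluded).
#' @return the depth map with `qc_pass` filled in and a `qc_report`
#'   attribute (list: thickness stats, failing fraction, voxel counts,
#'   dispersion-flag count, skipped segments).
#' @export
qc_filter <- function(depthmap, max_thickness_mm = 4, len_cv_max = 0.5) {
  labeled <- !is.na(depthmap$thickness)
  pass <- labeled & depthmap$thickness < max_thickness_mm
  depthmap$qc_pass <- pass
  disp <- labeled & depthmap$len_cv > len_cv_max
  attr(depthmap, "qc_report") <- list(
    thickness = summary(depthmap$thickness[labeled]),
    frac_fail_thickness = mean(!pass[labeled]),
    n_gm = nrow(depthmap), n_labeled = sum(labeled),
    n_dispersion_flagged = sum(disp),
    skipped_segments = attr(depthmap, "skipped_segments"))
  depthmap
}
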