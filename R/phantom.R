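#' Configuration for the folded cortical-ribbon phantom
#'
#' The phantom is a sinusoidally folded slab: the WM surface is the height
#' field `z = A sin(2 pi x / lambda) sin(2 pi y / lambda)` over a rectangular
#' domain, and the pial (GM) surface is its offset along local surface normals
#' by the cortical thickness. `fold_amp = 0` gives a flat slab.
#'
#' @param fov field of view per axis (mm), length 3. The x/y extent is the
#'   mesh domain; the z extent is the voxel-grid depth coverage.
#' @param voxel isotropic voxel size (mm); default 0.7 as acquired at 7 T.
#' @param fold_amp fold amplitude `A` (mm); 0 = flat-slab mode.
#' @param fold_wavelength fold wavelength `lambda` (mm).
#' @param thickness cortical thickness (mm): a scalar or a `function(x, y)`
#'   returning thickness at each surface point. Default 2.5 mm, typical of V1.
#' @param edge mesh edge length (mm). Default 0.35, half a voxel.
#' @param seed integer seed recorded with the phantom (geometry itself is
#'   deterministic).
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(fov = c(20, 20, 8), voxel = 0.7,
                           fold_amp = 2, fold_wavelength = 20,
                           thickness = 2.5, edge = 0.35, seed = 1L) {
  stopifnot(length(fov) == 3, all(fov > 0), voxel > 0,
            fold_amp >= 0, fold_wavelength > 0, edge > 0)
  if (is.numeric(thickness) && any(thickness <= 0))
    stop("thickness must be positive everywhere")
  structure(list(fov = as.numeric(fov), voxel = voxel, fold_amp = fold_amp,
                 fold_wavelength = fold_wavelength, thickness = thickness,
                 edge = edge, seed = as.integer(seed)),
            class = "phantom_config")
}

thickness_fun <- function(config) {
  if (is.function(config$thickness)) config$thickness
  else {
    t0 <- config$thickness
    function(x, y) rep_len(t0, length(x))
  }
}

# height field and analytic derivatives of the WM surface
wm_height <- function(config, x, y) {
  k <- 2 * pi / config$fold_wavelength
  config$fold_amp * sin(k * x) * sin(k * y)
}

wm_gradient <- function(config, x, y) {
  k <- 2 * pi / config$fold_wavelength
  A <- config$fold_amp
  cbind(dx = A * k * cos(k * x) * sin(k * y),
        dy = A * k * sin(k * x) * cos(k * y))
}

wm_unit_normal <- function(config, x, y) {
  g <- wm_gradient(config, x, y)
  n <- cbind(-g[, 1], -g[, 2], 1)
  n / sqrt(rowSums(n^2))
}

#' Build the paired WM/GM meshes of the ribbon phantom
#'
#' Triangulates the WM height field on a regular grid and offsets each vertex
#' along the analytic surface normal by the local thickness to obtain the GM
#' (pial) surface; vertex `i` of the GM mesh corresponds to vertex `i` of the
#' WM mesh, so the connecting segments have length exactly equal to the
#' thickness field.
#'
#' @param config a [phantom_config()].
#' @return A [surface_pair()].
#' @details If the thickness is too large relative to the fold curvature the
#'   normal offset folds over itself (a GM face flips orientation relative to
#'   its WM parent); this is detected and rejected with an error.
#' @export
make_ribbon_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  xs <- seq(0, config$fov[1], by = config$edge)
  ys <- seq(0, config$fov[2], by = config$edge)
  g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  z <- wm_height(config, g$x, g$y)
  vw <- cbind(g$x, g$y, z)
  nrm <- wm_unit_normal(config, g$x, g$y)
  th <- thickness_fun(config)(g$x, g$y)
  vg <- vw + nrm * th

  nx <- length(xs); ny <- length(ys)
  # two triangles per grid cell, consistent winding (normals toward +z)
  i0 <- rep(seq_len(nx - 1), ny - 1) + rep((seq_len(ny - 1) - 1) * nx,
                                           each = nx - 1)
  f <- rbind(cbind(i0, i0 + 1L, i0 + nx),
             cbind(i0 + 1L, i0 + nx + 1L, i0 + nx))
  wm <- lam_mesh(vw, f)
  gm <- lam_mesh(vg, f, validate = FALSE)

  # self-intersection guard: offsetting by more than the local radius of
  # curvature flips GM faces against their WM parents
  dots <- rowSums(face_normals(wm) * face_normals(gm))
  if (any(!is.finite(dots)) || any(dots <= 0))
    stop("GM surface self-intersects: thickness too large for the fold ",
         "curvature; reduce thickness or fold amplitude")
  validate_mesh(gm)
  surface_pair(wm, gm)
}

#' Voxelize a phantom: tissue labels and ground-truth depth
#'
#' Classifies every voxel center of an axis-aligned 0.7 mm (default) grid as
#' white matter, gray matter or outside by its signed distance along the local
#' WM normal, and records for each GM voxel the true relative depth
#' (distance above the WM surface along the normal, divided by local
#' thickness, 0 at the WM surface and 1 at the pial surface), the true
#' thickness, and a deterministic retinotopic tag (eccentricity band 1-3, for
#' 1-3, 3-6 and 6-9 degrees, and one of 8 polar-angle wedges) mapped from the
#' in-plane position with the domain center as the fovea.
#'
#' @param pair a [surface_pair()] from [make_ribbon_phantom()].
#' @param config the [phantom_config()] that generated `pair` (carries the
#'   analytic surface used for exact truth).
#' @param ecc_scale degrees of visual eccentricity per mm of cortex for the
#'   synthetic retinotopic tag (default 0.9 deg/mm so the default 20 mm domain
#'   spans roughly 9 degrees).
#' @return A list with `tissue` (a `tissue_volume`: integer 3D array with
#'   0 = outside, 1 = WM, 2 = GM, plus `voxel` and `origin`) and `truth`
#'   (a data frame, one row per GM voxel: grid indices `i,j,k`, world
#'   coordinates, `rel_depth`, `thickness`, `ecc_band`, `polar_wedge`).
#' @export
voxelize <- function(pair, config, ecc_scale = 0.9) {
  stopifnot(inherits(pair, "surface_pair"), inherits(config, "phantom_config"))
  vox <- config$voxel
  dims <- as.integer(ceiling(config$fov / vox))
  allv <- rbind(pair$wm$vertices, pair$gm$vertices)
  zmid <- (min(allv[, 3]) + max(allv[, 3])) / 2
  origin <- c(0, 0, zmid - dims[3] * vox / 2)
  hi <- origin + dims * vox
  vw <- pair$wm$vertices
  # the laminar (z) axis must cover both surfaces; laterally only the WM
  # domain matters (GM vertices may overhang along tilted normals and clip)
  if (any(allv[, 3] < origin[3]) || any(allv[, 3] > hi[3]) ||
      any(vw[, 1] < origin[1] - 1e-9) || any(vw[, 1] > hi[1] + 1e-9) ||
      any(vw[, 2] < origin[2] - 1e-9) || any(vw[, 2] > hi[2] + 1e-9))
    stop(sprintf(
      "voxel grid [%.2f..%.2f, %.2f..%.2f, %.2f..%.2f] mm does not cover the meshes",
      origin[1], hi[1], origin[2], hi[2], origin[3], hi[3]))

  ctr <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 0.5) * vox)
  gidx <- expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                      k = seq_len(dims[3]), KEEP.OUT.ATTRS = FALSE)
  px <- ctr[[1]][gidx$i]; py <- ctr[[2]][gidx$j]; pz <- ctr[[3]][gidx$k]

  cls <- classify_points(config, px, py, pz)
  lab <- integer(nrow(gidx))                # 0 outside
  lab[cls$label == "wm"] <- 1L
  lab[cls$label == "gm"] <- 2L
  labels <- array(lab, dim = dims)
  tissue <- structure(list(labels = labels, voxel = vox, origin = origin,
                           dims = dims), class = "tissue_volume")

  sel <- lab == 2L
  cx <- config$fov[1] / 2; cy <- config$fov[2] / 2
  ecc <- sqrt((px[sel] - cx)^2 + (py[sel] - cy)^2) * ecc_scale
  band <- ifelse(ecc < 1, 0L, ifelse(ecc < 3, 1L, ifelse(ecc < 6, 2L,
                 ifelse(ecc <= 9, 3L, 0L))))
  ang <- atan2(py[sel] - cy, px[sel] - cx) %% (2 * pi)
  wedge <- pmin(8L, as.integer(ang / (pi / 4)) + 1L)
  truth <- data.frame(i = gidx$i[sel], j = gidx$j[sel], k = gidx$k[sel],
                      x = px[sel], y = py[sel], z = pz[sel],
                      rel_depth = cls$s[sel] / cls$thickness[sel],
                      thickness = cls$thickness[sel],
                      ecc_band = band, polar_wedge = wedge)
  class(truth) <- c("depth_truth", class(truth))
  list(tissue = tissue, truth = truth)
}

# Classify points against the analytic ribbon: fixed-point search for the
# foot point on the WM surface, signed offset s along the local normal.
classify_points <- function(config, px, py, pz, iters = 30L) {
  u <- px; v <- py
  s <- numeric(length(px))
  for (it in seq_len(iters)) {
    n <- wm_unit_normal(config, u, v)
    z0 <- wm_height(config, u, v)
    dx <- px - u; dy <- py - v; dz <- pz - z0
    s <- dx * n[, 1] + dy * n[, 2] + dz * n[, 3]
    fu <- px - s * n[, 1]
    fv <- py - s * n[, 2]
    u <- pmin(pmax(fu, 0), config$fov[1])
    v <- pmin(pmax(fv, 0), config$fov[2])
  }
  n <- wm_unit_normal(config, u, v)
  z0 <- wm_height(config, u, v)
  dx <- px - u; dy <- py - v; dz <- pz - z0
  s <- dx * n[, 1] + dy * n[, 2] + dz * n[, 3]
  lat2 <- (dx - s * n[, 1])^2 + (dy - s * n[, 2])^2 + (dz - s * n[, 3])^2
  th <- thickness_fun(config)(u, v)
  label <- rep("outside", length(px))
  ok <- sqrt(lat2) < 1e-3
  label[ok & s < 0] <- "wm"
  label[ok & s >= 0 & s <= th] <- "gm"
  list(label = label, s = s, thickness = th, u = u, v = v)
}

#' Linear (column-major) index of grid voxels
#' @param tissue a `tissue_volume`.
#' @param i,j,k 1-based grid indices.
#' @return integer linear indices into the label array.
#' @keywords internal
voxel_linear_index <- function(tissue, i, j, k) {
  d <- tissue$dims
  as.integer((k - 1L) * d[1] * d[2] + (j - 1L) * d[1] + i)
}

#' Voxel center world coordinates
#' @inheritParams voxel_linear_index
#' @return `n x 3` matrix of world coordinates (mm).
#' @keywords internal
voxel_centers <- function(tissue, i, j, k) {
  cbind(tissue$origin[1] + (i - 0.5) * tissue$voxel,
        tissue$origin[2] + (j - 0.5) * tissue$voxel,
        tissue$origin[3] + (k - 0.5) * tissue$voxel)
}
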