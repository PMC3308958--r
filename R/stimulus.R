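#' Hexagonal aperture grid for occluded stimuli
#'
#' Apertures are circles of `diameter` degrees of visual angle, packed on a
#' hexagonal lattice with center spacing `diameter + gap`, inside a square
#' field spanning `+/- subtense` degrees. Only apertures fully contained in
#' the field are kept. When a stimulus image is masked, every pixel outside
#' the apertures is set to mean gray (the occluder is an inferred mask, not a
#' rendered surface).
#'
#' @param diameter aperture diameter (deg), default 2.
#' @param gap gap between aperture rims (deg), in 0.7-1.0 for the stimuli
#'   modelled here.
#' @param subtense half-width of the square field (deg), default 7.6.
#' @return Object of class `aperture_grid`: data frame of centers
#'   (`x`, `y`, deg) with attributes `diameter`, `gap`, `spacing`, `subtense`.
#' @export
make_aperture_grid <- function(diameter = 2, gap = 0.8, subtense = 7.6) {
  stopifnot(diameter > 0, gap >= 0)
  if (diameter > 2 * subtense) stop("aperture diameter exceeds the field")
  s <- diameter + gap
  r <- diameter / 2
  dy <- s * sqrt(3) / 2
  jmax <- floor((subtense - r) / dy)
  rows <- seq(-jmax, jmax)
  cen <- do.call(rbind, lapply(rows, function(j) {
    off <- if (j %% 2 == 0) 0 else s / 2
    imax <- floor((subtense - r - off) / s)
    imin <- -floor((subtense - r + off) / s)
    if (imax < imin) return(NULL)
    cbind(x = seq(imin, imax) * s + off, y = j * dy)
  }))
  g <- as.data.frame(cen)
  attr(g, "diameter") <- diameter
  attr(g, "gap") <- gap
  attr(g, "spacing") <- s
  attr(g, "subtense") <- subtense
  class(g) <- c("aperture_grid", class(g))
  g
}

#' Convert degrees of visual angle to pixel coordinates
#'
#' Pixel grid fixed at `npx` x `npx` over `+/- subtense` degrees; pixel (1,1)
#' is the lower-left corner, coordinates refer to pixel centers.
#' @param deg positions in degrees.
#' @param subtense field half-width (deg).
#' @param npx image side in pixels, default 512.
#' @return positions in (fractional) pixel units.
#' @export
deg_to_px <- function(deg, subtense = 7.6, npx = 512L) {
  (deg + subtense) / (2 * subtense) * npx + 0.5
}

px_per_deg <- function(subtense = 7.6, npx = 512L) npx / (2 * subtense)

#' Procedural "object" image (synthetic stand-in)
#'
#' Generates a seeded drawing of random smooth polylines on a white
#' background, lightly anti-aliased, emulating the luminance structure of
#' colored line drawings of objects. These are synthetic stand-ins: only
#' their aperture-level statistics (contrast, orientation content) matter to
#' the analyses here.
#'
#' @param seed integer seed.
#' @param npx image side (pixels).
#' @param n_strokes number of polyline strokes.
#' @param background background luminance in 0-1 (white = 1).
#' @return `npx x npx` luminance matrix in 0-1.
#' @export
make_object_image <- function(seed = 1L, npx = 512L, n_strokes = 12L,
                              background = 1) {
  rng <- local_rng(seed)
  img <- matrix(background, npx, npx)
  cx <- npx / 2
  for (s in seq_len(n_strokes)) {
    npts <- rng$int(4L, 8L)
    # random walk around the image center
    pts <- matrix(0, npts, 2)
    pts[1, ] <- cx + rng$unif(2, -npx / 4, npx / 4)
    for (p in 2:npts)
      pts[p, ] <- pts[p - 1, ] + rng$unif(2, -npx / 6, npx / 6)
    pts <- pmin(pmax(pts, 3), npx - 2)
    lum <- rng$unif(1, 0, 0.6)          # dark stroke on white ground
    wid <- rng$unif(1, 2, 4)
    for (p in 2:npts)
      img <- draw_segment(img, pts[p - 1, ], pts[p, ], lum, wid)
  }
  # anti-alias to the smoothness of rasterized naturalistic drawings, so
  # interpolation during aperture rotation resamples rather than destroys
  # the luminance structure
  blur_matrix(img, sigma = 1.5)
}

# stamp an anti-aliased thick segment into the image
draw_segment <- function(img, a, b, lum, width) {
  npx <- nrow(img)
  L <- sqrt(sum((b - a)^2))
  n <- max(2L, ceiling(L))
  tx <- a[1] + (b[1] - a[1]) * seq(0, 1, length.out = n)
  ty <- a[2] + (b[2] - a[2]) * seq(0, 1, length.out = n)
  r <- ceiling(width)
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= width^2, , drop = FALSE]
  xi <- pmin(pmax(round(rep(tx, each = nrow(off)) + off$dx), 1), npx)
  yi <- pmin(pmax(round(rep(ty, each = nrow(off)) + off$dy), 1), npx)
  img[cbind(xi, yi)] <- lum
  img
}

blur_matrix <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gauss_kernel_1d(sigma)
  sep_convolve_2d(img, k)
}

gauss_kernel_1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- -radius:radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable 2D convolution with edge renormalization
sep_convolve_2d <- function(img, k) {
  conv1 <- function(m, k) {
    r <- (length(k) - 1) / 2
    n <- nrow(m)
    pad <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
    ones <- rbind(matrix(0, r, ncol(m)), matrix(1, n, ncol(m)),
                  matrix(0, r, ncol(m)))
    out <- matrix(0, n, ncol(m)); wt <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * pad[i:(i + n - 1), , drop = FALSE]
      wt <- wt + k[i] * ones[i:(i + n - 1), , drop = FALSE]
    }
    out / wt
  }
  t(conv1(t(conv1(img, k)), k))
}

#' Draw rotation-scramble angles
#'
#' Angles are drawn with equal probability from two uniform distributions,
#' on 60-120 degrees or on -120 to -60 degrees, so the average absolute
#' rotation is 90 degrees.
#'
#' @param n number of draws.
#' @param seed integer seed.
#' @return numeric vector of angles in degrees.
#' @export
draw_scramble_angles <- function(n, seed = 1L) {
  rng <- local_rng(seed)
  mag <- rng$unif(n, 60, 120)
  sgn <- ifelse(rng$unif(n) < 0.5, 1, -1)
  sgn * mag
}

#' Rotation-scramble the aperture contents of an image
#'
#' The content of each aperture that contains part of an object (any pixel
#' deviating from mean gray/background beyond `tol`) is rotated about the
#' aperture center by an independent draw from the scramble mixture
#' ([draw_scramble_angles()]), using bilinear interpolation; content rotated
#' across the rim stays clipped to the circular aperture (a rotation about
#' the center maps the disc onto itself). Empty apertures are untouched.
#' Deterministic for a fixed seed.
#'
#' @param image luminance matrix (square), pixel (1,1) at lower-left.
#' @param grid an [make_aperture_grid()].
#' @param seed integer seed.
#' @param tol deviation from the aperture mean defining "contains an object".
#' @return list with `image` (scrambled matrix) and `angles` (named by
#'   aperture row index; NA for empty apertures).
#' @export
scramble_image <- function(image, grid, seed = 1L, tol = 0.02) {
  npx <- nrow(image)
  stopifnot(ncol(image) == npx)
  subtense <- attr(grid, "subtense")
  rpx <- attr(grid, "diameter") / 2 * px_per_deg(subtense, npx)
  angles <- rep(NA_real_, nrow(grid))
  draws <- draw_scramble_angles(nrow(grid), seed = seed)
  out <- image
  for (a in seq_len(nrow(grid))) {
    cx <- deg_to_px(grid$x[a], subtense, npx)
    cy <- deg_to_px(grid$y[a], subtense, npx)
    xi <- max(1L, floor(cx - rpx)):min(npx, ceiling(cx + rpx))
    yi <- max(1L, floor(cy - rpx)):min(npx, ceiling(cy + rpx))
    gx <- rep(xi, times = length(yi)); gy <- rep(yi, each = length(xi))
    inside <- (gx - cx)^2 + (gy - cy)^2 <= rpx^2
    gx <- gx[inside]; gy <- gy[inside]
    if (!length(gx)) next
    vals <- image[cbind(gx, gy)]
    if (max(abs(vals - mean(vals))) <= tol) next   # empty aperture: no-op
    th <- draws[a] * pi / 180
    # rotate up to a 1.5 px margin inside the rim so bilinear sampling
    # never blends in occluder gray from outside the aperture; the thin
    # rim annulus keeps its original content
    core <- (gx - cx)^2 + (gy - cy)^2 <= (rpx - 1.5)^2
    rx <- gx[core]; ry <- gy[core]
    sx <- cx + cos(th) * (rx - cx) + sin(th) * (ry - cy)
    sy <- cy - sin(th) * (rx - cx) + cos(th) * (ry - cy)
    out[cbind(rx, ry)] <- bilinear_sample(image, sx, sy)
    angles[a] <- draws[a]
  }
  list(image = out, angles = angles)
}

bilinear_sample <- function(img, x, y) {
  npx <- nrow(img); npy <- ncol(img)
  x <- pmin(pmax(x, 1), npx); y <- pmin(pmax(y, 1), npy)
  x0 <- pmin(floor(x), npx - 1L); y0 <- pmin(floor(y), npy - 1L)
  fx <- x - x0; fy <- y - y0
  img[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    img[cbind(x0 + 1, y0)] * fx * (1 - fy) +
    img[cbind(x0, y0 + 1)] * (1 - fx) * fy +
    img[cbind(x0 + 1, y0 + 1)] * fx * fy
}

#' Mask an image with an aperture grid
#'
#' Pixels outside every aperture are set to `gray`.
#' @inheritParams scramble_image
#' @param gray occluder luminance (mean gray), default 0.5.
#' @return masked luminance matrix.
#' @export
mask_with_apertures <- function(image, grid, gray = 0.5) {
  npx <- nrow(image)
  subtense <- attr(grid, "subtense")
  rpx <- attr(grid, "diameter") / 2 * px_per_deg(subtense, npx)
  xs <- matrix(seq_len(npx), npx, npx)
  ys <- t(xs)
  keep <- matrix(FALSE, npx, npx)
  for (a in seq_len(nrow(grid))) {
    cx <- deg_to_px(grid$x[a], subtense, npx)
    cy <- deg_to_px(grid$y[a], subtense, npx)
    keep <- keep | ((xs - cx)^2 + (ys - cy)^2 <= rpx^2)
  }
  out <- matrix(gray, npx, npx)
  out[keep] <- image[keep]
  out
}

#' RMS contrast of an image patch
#'
#' Standard deviation of luminance divided by mean luminance (population
#' standard deviation, so a half-black/half-white patch gives exactly 1).
#'
#' @param patch luminance values in 0-1.
#' @return scalar RMS contrast.
#' @export
rms_contrast <- function(patch) {
  m <- mean(patch)
  if (abs(m) < .Machine$double.eps^0.5)
    stop("RMS contrast undefined for (near-)zero-mean luminance")
  sqrt(mean((patch - m)^2)) / m
}

#' Orientation-band power of a 45 x 45 patch
#'
#' The patch is vignetted by a centered Gaussian (sigma 8 px) to avoid edge
#' artifacts, Fourier transformed, and the power (squared magnitude,
#' excluding DC) is averaged within four 45-degree orientation wedges
#' centered on horizontal, 45, vertical and 135 degrees. Band orientation
#' refers to the image feature (stripe) orientation, perpendicular to the
#' spatial-frequency vector.
#'
#' @param patch luminance matrix, must be 45 x 45.
#' @param vignette_sigma Gaussian vignette sigma in pixels, default 8.
#' @return named numeric vector of mean band powers
#'   (`horizontal`, `oblique45`, `vertical`, `oblique135`).
#' @export
orientation_power <- function(patch, vignette_sigma = 8) {
  if (!all(dim(patch) == c(45L, 45L)))
    stop("patch must be 45 x 45 pixels")
  n <- 45L
  ctr <- (n + 1) / 2
  g <- exp(-((seq_len(n) - ctr)^2) / (2 * vignette_sigma^2))
  vp <- (patch - mean(patch)) * outer(g, g)
  P <- Mod(stats::fft(vp))^2
  fx <- ifelse(seq_len(n) - 1 > n / 2, seq_len(n) - 1 - n, seq_len(n) - 1)
  FX <- matrix(fx, n, n); FY <- t(FX)
  # stripe orientation is perpendicular to the frequency vector
  ori <- (atan2(FY, FX) * 180 / pi + 90) %% 180
  band <- findInterval(((ori + 22.5) %% 180), c(0, 45, 90, 135, 180))
  keep <- !(FX == 0 & FY == 0)
  pw <- vapply(1:4, function(b) mean(P[keep & band == b]), numeric(1))
  names(pw) <- c("horizontal", "oblique45", "vertical", "oblique135")
  pw
}

#' Image presentation schedule within a stimulus block
#'
#' Each stimulus block is filled back-to-back with briefly flashed images.
#' @param block_s block duration (s), default 16.
#' @param image_dur_s single-image duration (s), default 0.25.
#' @return data frame of image onsets (s, block-relative); 64 rows for the
#'   defaults.
#' @export
presentation_schedule <- function(block_s = 16, image_dur_s = 0.25) {
  n <- block_s / image_dur_s
  if (abs(n - round(n)) > 1e-9)
    stop("image duration must divide the block length")
  data.frame(onset_s = (seq_len(round(n)) - 1) * image_dur_s,
             duration_s = image_dur_s)
}

# small self-contained RNG wrapper so seeded draws never disturb the
# caller's .Random.seed
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- f()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(
    unif = function(n, min = 0, max = 1) with_state(function() stats::runif(n, min, max)),
    norm = function(n, mean = 0, sd = 1) with_state(function() stats::rnorm(n, mean, sd)),
    int = function(lo, hi) with_state(function() sample(lo:hi, 1L)),
    sample = function(x, size = length(x), replace = FALSE)
      with_state(function() sample(x, size, replace))
  )
}
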