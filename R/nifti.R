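#' Minimal NIfTI-1 volume I/O
#'
#' Self-contained reader/writer for single-file NIfTI-1 (`.nii`, or
#' `.nii.gz` via a gzip connection), covering the little-endian float32
#' volumes this package produces: axis-aligned grids with an sform
#' translation, no intensity scaling, no extensions. The reader also accepts
#' int16/int32/float64 data. Written because no NIfTI package is available
#' in the target R library; not a general-purpose implementation.
#'
#' @param x numeric array (3D or 4D).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param voxel voxel size (mm), scalar (isotropic) or length-3.
#' @param origin world position of the corner of voxel (1,1,1) (mm); the
#'   sform places voxel centers at `origin + (index - 0.5) * voxel`.
#' @param TR repetition time (s), stored in `pixdim[5]` for 4D data.
#' @return `write_nifti` returns `path` invisibly; `read_nifti` returns the
#'   data array with attributes `voxel`, `origin` and `TR`.
#' @export
write_nifti <- function(x, path, voxel = 0.7, origin = c(0, 0, 0), TR = 2) {
  x <- as.array(x)
  nd <- length(dim(x))
  stopifnot(nd %in% c(3L, 4L))
  voxel <- rep_len(voxel, 3)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi2 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  wi4 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wpad <- function(n) writeBin(raw(n), con)
  wstr <- function(s, n) {
    b <- charToRaw(s)
    writeBin(c(b[seq_len(min(length(b), n))], raw(max(0, n - length(b)))), con)
  }
  wi4(348L)                                   # sizeof_hdr
  wpad(34)                                    # data_type, db_name, extents, ...
  writeBin(as.raw(114L), con)                 # regular = 'r' (unused)
  wpad(1)                                     # dim_info
  wi2(c(nd, dim(x), rep(1L, 7 - nd)))         # dim[8]
  wf(c(0, 0, 0))                              # intent_p1..3
  wi2(0L)                                     # intent_code
  wi2(16L)                                    # datatype = float32
  wi2(32L)                                    # bitpix
  wi2(0L)                                     # slice_start
  wf(c(1, voxel, if (nd == 4) TR else 1, 1, 1, 1))   # pixdim[8]
  wf(352)                                     # vox_offset
  wf(1); wf(0)                                # scl_slope, scl_inter
  wi2(0L); wpad(1)                            # slice_end, slice_code
  writeBin(as.raw(10L), con)                  # xyzt_units: mm + sec
  wf(c(0, 0, 0, 0))                           # cal_max/min, slice_dur, toffset
  wi4(c(0L, 0L))                              # glmax, glmin
  wstr("laminarfmri", 80)                     # descrip
  wpad(24)                                    # aux_file
  wi2(0L); wi2(1L)                            # qform_code, sform_code
  wf(c(0, 0, 0)); wf(c(0, 0, 0))              # quaterns, qoffsets
  ctr0 <- origin + 0.5 * voxel                # center of voxel (1,1,1)
  wf(c(voxel[1], 0, 0, ctr0[1]))              # srow_x
  wf(c(0, voxel[2], 0, ctr0[2]))              # srow_y
  wf(c(0, 0, voxel[3], ctr0[3]))              # srow_z
  wpad(16)                                    # intent_name
  wstr("n+1", 4)                              # magic
  wpad(4)                                     # extension flag = none
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  ri2 <- function(off, n = 1) readBin(hdr[(off + 1):(off + 2 * n)], "integer",
                                      n, size = 2, endian = "little")
  ri4 <- function(off, n = 1) readBin(hdr[(off + 1):(off + 4 * n)], "integer",
                                      n, size = 4, endian = "little")
  rf <- function(off, n = 1) readBin(hdr[(off + 1):(off + 4 * n)], "numeric",
                                     n, size = 4, endian = "little")
  if (ri4(0) != 348L) stop("not a little-endian NIfTI-1 file: ", path)
  dims <- ri2(40, 8)
  nd <- dims[1]
  d <- dims[2:(1 + nd)]
  datatype <- ri2(70)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108)
  srow <- rbind(rf(280, 4), rf(296, 4), rf(312, 4))
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(d)
  dat <- switch(as.character(datatype),
    `2` = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    `4` = as.numeric(readBin(con, "integer", n, size = 2, endian = "little")),
    `8` = as.numeric(readBin(con, "integer", n, size = 4, endian = "little")),
    `16` = readBin(con, "numeric", n, size = 4, endian = "little"),
    `64` = readBin(con, "numeric", n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype: ", datatype))
  slope <- rf(112); inter <- rf(116)
  if (slope != 0 && !(slope == 1 && inter == 0)) dat <- dat * slope + inter
  x <- array(dat, dim = d)
  voxel <- pixdim[2:4]
  attr(x, "voxel") <- voxel
  attr(x, "origin") <- srow[, 4] - 0.5 * voxel
  attr(x, "TR") <- if (nd == 4) pixdim[5] else NA_real_
  x
}
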