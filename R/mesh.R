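#' Triangulated surface mesh
#'
#' A minimal triangle-mesh container: an `n x 3` matrix of vertex positions in
#' millimetres (right-handed world frame) and an `m x 3` integer matrix of
#' 1-based vertex indices, one row per triangular face.
#'
#' @param vertices numeric matrix, `n x 3`, vertex positions (mm).
#' @param faces integer matrix, `m x 3`, vertex index triples.
#' @param validate check invariants (indices in range, no orphan vertices,
#'   no zero-area triangles)?
#' @return An object of class `lam_mesh` with elements `vertices` and `faces`.
#' @export
lam_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices and faces must both have 3 columns")
  m <- structure(list(vertices = vertices, faces = faces), class = "lam_mesh")
  if (validate) validate_mesh(m)
  m
}

validate_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (any(f < 1L) || any(f > nrow(v)))
    stop("face indices out of range")
  if (!all(seq_len(nrow(v)) %in% f))
    stop("mesh contains vertices referenced by no face")
  a <- face_areas(mesh)
  if (any(a <= .Machine$double.eps))
    stop("mesh contains degenerate (zero-area) triangles")
  invisible(mesh)
}

face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

face_normals <- function(mesh, normalize = TRUE) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  if (normalize) n / sqrt(rowSums(n^2))
  else n
}

#' Area-weighted vertex normals
#'
#' Vertex normals computed as the normalized sum of (unnormalized) incident
#' face normals; the face-area weighting is implicit in the cross-product
#' magnitude. Orientation follows the face winding.
#'
#' @param mesh a [lam_mesh()].
#' @return `n x 3` matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh, normalize = FALSE)
  idx <- as.vector(mesh$faces)            # c(f[,1], f[,2], f[,3])
  agg <- rowsum(rbind(fn, fn, fn), idx)
  n <- matrix(0, nrow(mesh$vertices), 3)
  n[as.integer(rownames(agg)), ] <- agg
  n / sqrt(rowSums(n^2))
}

#' Matched white-matter/pial surface pair
#'
#' Bundles a WM and a GM (pial) mesh with implicit vertex correspondence:
#' vertex `i` of the WM mesh matches vertex `i` of the GM mesh, and the
#' connecting segments define local cortical thickness.
#'
#' @param wm,gm [lam_mesh()] objects with equal vertex and face counts.
#' @return Object of class `surface_pair`.
#' @export
surface_pair <- function(wm, gm) {
  if (nrow(wm$vertices) != nrow(gm$vertices) ||
      nrow(wm$faces) != nrow(gm$faces))
    stop("WM and GM meshes must have the same numbers of vertices and faces")
  len <- sqrt(rowSums((gm$vertices - wm$vertices)^2))
  if (any(len <= 0))
    stop("every WM->GM connecting segment must have positive length")
  structure(list(wm = wm, gm = gm), class = "surface_pair")
}

#' Read / write Wavefront OBJ meshes
#'
#' Plain-text OBJ with `v` and triangular `f` records only.
#'
#' @param mesh a [lam_mesh()].
#' @param path file path.
#' @return `write_obj` returns `path` invisibly; `read_obj` returns a
#'   [lam_mesh()].
#' @export
write_obj <- function(mesh, path) {
  v <- sprintf("v %.9g %.9g %.9g",
               mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  f <- sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  writeLines(c(v, f), path)
  invisible(path)
}

#' @rdname write_obj
#' @export
read_obj <- function(path) {
  ln <- readLines(path)
  vl <- ln[startsWith(ln, "v ")]
  fl <- ln[startsWith(ln, "f ")]
  if (!length(vl) || !length(fl)) stop("no vertices or faces in OBJ file: ", path)
  v <- matrix(as.numeric(unlist(strsplit(sub("^v +", "", vl), " +"))),
              ncol = 3, byrow = TRUE)
  fparts <- lapply(strsplit(sub("^f +", "", fl), " +"),
                   function(x) as.integer(sub("/.*", "", x)))
  if (any(lengths(fparts) != 3L)) stop("only triangular faces are supported")
  f <- matrix(unlist(fparts), ncol = 3, byrow = TRUE)
  lam_mesh(v, f)
}
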