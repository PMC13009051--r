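# Triangulated boundary surfaces of segmentation masks.
#
# The surface is the 0.5 iso-level of the (optionally anti-aliased) indicator
# field, triangulated by marching tetrahedra in C++. Iso-surfacing the *raw*
# binary field yields the axis-aligned staircase surface, which overestimates
# the area of smooth shapes by ~8% and would bias surface regularity and
# sphericity downward; a mild Gaussian anti-aliasing of the indicator
# (default sigma = 1 voxel) removes almost all of that bias at sub-percent
# cost in volume for lesions larger than ~10 voxels in radius.

#' Construct a surface mesh
#'
#' @param vertices Numeric matrix (n x 3) of vertex positions in mm.
#' @param faces Integer matrix (m x 3) of 1-based vertex indices with
#'   consistent outward orientation.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices and faces must have three columns")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces, area ", signif(mesh_area(x), 6), " mm^2\n", sep = "")
  invisible(x)
}

#' Extract the boundary surface of a mask
#'
#' Triangulates the 0.5 iso-surface of the foreground indicator in physical
#' (mm) coordinates. The mask is padded internally so surfaces are closed even
#' when the foreground touches the array border; the output mesh is watertight
#' (every edge shared by exactly two faces) and consistently outward-oriented.
#'
#' @param mask A `seg_mask`.
#' @param smooth_sigma Gaussian anti-aliasing width in voxels applied to the
#'   indicator before iso-surfacing; `0` disables it and triangulates the raw
#'   binary field. If smoothing leaves no 0.5 crossing (very small masks), the
#'   raw field is used automatically.
#' @return A [surface_mesh()].
#' @export
extract_mesh <- function(mask, smooth_sigma = 1) {
  stopifnot(inherits(mask, "seg_mask"))
  if (smooth_sigma < 0) stop("smooth_sigma must be >= 0")
  pad <- max(1L, as.integer(ceiling(3 * smooth_sigma)) + 1L)
  dm <- dim(mask$voxels)
  field <- array(0, dm + 2L * pad)
  field[pad + seq_len(dm[1]), pad + seq_len(dm[2]), pad + seq_len(dm[3])] <-
    mask$voxels
  if (smooth_sigma > 0) {
    sm <- cpp_gaussian_smooth(field, dim(field), smooth_sigma)
    if (max(sm) > 0.5) field <- sm   # else: mask too small, keep raw indicator
  }
  res <- cpp_marching_tetrahedra(field, dim(field), 0.5, mask$spacing,
                                 mask$origin - pad * mask$spacing)
  surface_mesh(res$vertices, res$faces)
}

# every edge must appear in exactly two faces
.mesh_closed <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Mesh surface area
#'
#' Sum of triangle areas (half cross-product magnitudes).
#'
#' @param mesh A `surface_mesh`.
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(f) == 0L) stop("degenerate mesh: no faces")
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  area <- 0.5 * sum(sqrt(rowSums(cr^2)))
  if (area <= 0) stop("degenerate mesh: zero surface area")
  area
}

#' Mesh volume by the divergence theorem
#'
#' Signed sum of tetrahedra spanned by each face and the coordinate origin;
#' positive for a closed, outward-oriented mesh.
#'
#' @param mesh A closed, consistently oriented `surface_mesh`.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (!.mesh_closed(mesh))
    stop("mesh is not closed (an edge is not shared by exactly two faces)")
  v <- mesh$vertices; f <- mesh$faces
  v0 <- v[f[, 1], , drop = FALSE]
  v1 <- v[f[, 2], , drop = FALSE]
  v2 <- v[f[, 3], , drop = FALSE]
  cr <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
              v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
              v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  sum(rowSums(v0 * cr)) / 6
}

#' Export a mesh as ASCII PLY
#'
#' For external inspection (e.g. MeshLab).
#'
#' @param mesh A `surface_mesh`.
#' @param path Output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  write.table(format(mesh$vertices, trim = TRUE), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  write.table(cbind(3L, mesh$faces - 1L), con,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
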