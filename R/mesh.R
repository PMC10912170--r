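#' Triangle-mesh helpers
#'
#' Meshes are stored as a list with `vertices` (n x 3 matrix, micrometre
#' coordinates in (z, y, x) order) and `faces` (m x 3 integer matrix of
#' 1-based vertex indices, counter-clockwise seen from outside, i.e. outward
#' normals and positive signed volume).
#'
#' @name mesh-helpers
NULL

mesh_face_cross <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  u <- b - a
  w <- c_ - a
  cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
        u[, 3] * w[, 1] - u[, 1] * w[, 3],
        u[, 1] * w[, 2] - u[, 2] * w[, 1])
}

#' Per-face areas of a triangle mesh (um^2)
#' @param v vertex matrix, `f` face index matrix
#' @param f faces
#' @export
mesh_face_areas <- function(v, f) {
  cr <- mesh_face_cross(v, f)
  0.5 * sqrt(rowSums(cr^2))
}

#' Total surface area of a mesh (um^2)
#' @param v,f vertices and faces
#' @export
mesh_area <- function(v, f) sum(mesh_face_areas(v, f))

#' Signed volume of a closed mesh (um^3, positive for outward normals)
#' @param v,f vertices and faces
#' @export
mesh_volume <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  cr <- mesh_face_cross(v, f)
  sum(rowSums(a * cr)) / 6
}

#' Face centroids (m x 3)
#' @param v,f vertices and faces
#' @export
mesh_face_centroids <- function(v, f) {
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

edge_keys <- function(f) {
  # numeric edge key (exact for < 2^26 vertices)
  e1 <- c(f[, 1], f[, 2], f[, 3])
  e2 <- c(f[, 2], f[, 3], f[, 1])
  pmin(e1, e2) * 2^26 + pmax(e1, e2)
}

#' Number of boundary (unshared) edges of a mesh; 0 for a closed surface
#' @param f face matrix
#' @export
mesh_boundary_edges <- function(f) {
  s <- sort(edge_keys(f), method = "radix")
  r <- rle(s)
  sum(r$lengths == 1)
}

#' Euler characteristic V - E + F of a mesh (2 for a genus-0 closed surface)
#' @param v,f vertices and faces
#' @export
mesh_euler_characteristic <- function(v, f) {
  nrow(v) - length(unique(edge_keys(f))) + nrow(f)
}

# Iso-surface a (possibly smoothed) scalar field at `level` on an
# anisotropic grid; returns a mesh in um coordinates with outward normals
# (assumes field > level inside). origin_um shifts vertex coordinates.
mesh_from_field <- function(field, voxel_size, level = 0.5,
                            origin_um = c(0, 0, 0)) {
  m <- cpp_marching_tetrahedra(as.numeric(field), dim(field), level,
                               as.numeric(voxel_size))
  v <- m$vertices
  f <- m$faces
  if (nrow(f) == 0) return(NULL)
  if (mesh_volume(v, f) < 0) f <- f[, c(1, 3, 2), drop = FALSE]
  v <- sweep(v, 2, as.numeric(origin_um), "+")
  list(vertices = v, faces = f)
}

# Mesh a binary mask: pad so the surface closes, optionally Gaussian-smooth
# (sigma in voxels) to reduce staircase bias before iso-surfacing at 0.5.
mesh_from_mask <- function(mask, voxel_size, smooth_sigma_vox = 1,
                           origin_um = c(0, 0, 0)) {
  pad <- max(2L, ceiling(1.5 * max(smooth_sigma_vox)) + 1L)
  d <- dim(mask)
  field <- array(0, d + 2L * pad)
  field[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(mask != 0)
  if (any(smooth_sigma_vox > 0)) {
    sv <- rep_len(smooth_sigma_vox, 3)
    k <- lapply(sv, gaussian_kernel_1d)
    field <- cpp_sep_conv3d(as.numeric(field), dim(field),
                            k[[1]], k[[2]], k[[3]])
  }
  mesh_from_field(field, voxel_size, level = 0.5,
                  origin_um = origin_um - pad * voxel_size)
}

#' Signed distance from points to a closed mesh
#'
#' Unsigned distances come from an exact point-triangle search; the sign is
#' the generalized winding number (negative strictly inside). Also reports
#' the index of the nearest face.
#'
#' @param points n x 3 matrix of (z, y, x) um coordinates
#' @param v,f mesh vertices and faces
#' @return data.frame with `distance` (um, negative inside) and
#'   `nearest_face`
#' @export
signed_distance <- function(points, v, f) {
  points <- matrix(as.numeric(points), ncol = 3)
  r <- cpp_point_mesh_dist(points, v, f)
  data.frame(distance = r$distance, nearest_face = r$nearest_face)
}

#' Write a mesh as ASCII PLY
#' @param v,f vertices and faces
#' @param path output file. Coordinates are written as (x, y, z).
#' @export
write_ply <- function(v, f, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  # stored (z,y,x) -> file (x,y,z)
  writeLines(paste(v[, 3], v[, 2], v[, 1]), con)
  writeLines(paste(3, f[, 1] - 1, f[, 2] - 1, f[, 3] - 1), con)
  invisible(path)
}
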