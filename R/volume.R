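#' Labelled volume container
#'
#' Bundles per-channel instance-label arrays and (optionally) rendered
#' intensity arrays on a common anisotropic voxel grid. Axis order is
#' `(z, y, x)` throughout the package: array `dim` is `c(nz, ny, nx)` and
#' `voxel_size` gives the micrometre extent of one voxel along each of those
#' axes. World coordinates are in micrometres with the origin at the volume
#' corner; the centre of voxel `(i, j, k)` (1-based) sits at
#' `(i - 0.5, j - 0.5, k - 0.5) * voxel_size`.
#'
#' @param labels named list of 3D integer arrays (0 = background, positive
#'   integers are instance ids). Names give the channel role, e.g. `"neuron"`,
#'   `"microglia"`.
#' @param voxel_size numeric length-3, micrometres per voxel along (z, y, x).
#' @param channels optional named list of numeric intensity arrays with the
#'   same dimensions (e.g. a rendered `"puncta"` channel).
#' @return an object of class `labeled_volume`.
#' @export
labeled_volume <- function(labels, voxel_size, channels = list()) {
  stopifnot(is.list(labels), length(labels) >= 1, !is.null(names(labels)))
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(voxel_size <= 0)) {
    stopf("voxel_size must be 3 strictly positive values (z, y, x)")
  }
  dims <- dim(labels[[1]])
  for (nm in names(labels)) {
    a <- labels[[nm]]
    if (!identical(dim(a), dims)) stopf("label channel '%s' dimension mismatch", nm)
    if (any(a < 0)) stopf("label channel '%s' has negative labels", nm)
  }
  for (nm in names(channels)) {
    if (!identical(dim(channels[[nm]]), dims)) {
      stopf("intensity channel '%s' dimension mismatch", nm)
    }
  }
  structure(
    list(labels = labels, channels = channels, voxel_size = voxel_size,
         dims = dims),
    class = "labeled_volume"
  )
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("<labeled_volume> %d x %d x %d voxels (z,y,x), %.2f x %.2f x %.2f um\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat("  label channels:", paste(names(x$labels), collapse = ", "), "\n")
  if (length(x$channels)) {
    cat("  intensity channels:", paste(names(x$channels), collapse = ", "), "\n")
  }
  invisible(x)
}

# Euclidean distance (um) from every voxel centre to the nearest voxel
# centre of `mask` (logical/0-1 array), honouring anisotropic spacing.
distance_to_mask <- function(mask, voxel_size) {
  d2 <- cpp_sq_edt(as.integer(mask != 0), dim(mask), as.numeric(voxel_size))
  out <- sqrt(d2)
  dim(out) <- dim(mask)
  out
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma_vox))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Separable Gaussian smoothing of a 3D array; sigma_um recycled to 3 axes.
smooth_gaussian3d <- function(arr, sigma_um, voxel_size) {
  sigma_um <- rep_len(sigma_um, 3)
  sv <- sigma_um / voxel_size
  k <- lapply(sv, gaussian_kernel_1d)
  cpp_sep_conv3d(as.numeric(arr), dim(arr), k[[1]], k[[2]], k[[3]])
}

# 6-connectivity connected components of a logical 3D array
label_components <- function(mask) {
  cpp_label_components(as.integer(mask != 0), dim(mask))
}

# bounding box (index ranges) of a logical array, padded and clipped
mask_bbox <- function(mask, pad = 1L) {
  idx <- which(mask)
  if (!length(idx)) return(NULL)
  d <- dim(mask)
  co <- arrayInd(idx, d)
  lo <- pmax(1L, apply(co, 2, min) - pad)
  hi <- pmin(d, apply(co, 2, max) + pad)
  list(lo = lo, hi = hi)
}

# morphological opening of a logical mask by a metric ball of radius r (um)
open_mask <- function(mask, radius_um, voxel_size) {
  if (radius_um <= 0) return(mask != 0)
  d_bg <- distance_to_mask(!mask, voxel_size)   # distance to background
  eroded <- mask & (d_bg > radius_um)
  if (!any(eroded)) return(array(FALSE, dim(mask)))
  d_er <- distance_to_mask(eroded, voxel_size)
  d_er <= radius_um
}
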