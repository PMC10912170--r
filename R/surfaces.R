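#' Reconstruct per-cell surfaces from an instance-label volume
#'
#' Each label id becomes one closed triangulated mesh, obtained by
#' iso-surfacing the binary mask of the cell at the 0.5 level after a
#' one-voxel Gaussian smoothing (configurable; smoothing markedly reduces
#' the staircase area bias of anisotropic confocal grids). Cells touching
#' the volume border are flagged `truncated` and are excluded from
#' downstream pairing, mirroring standard stereological edge rules.
#'
#' @param vol a [labeled_volume()].
#' @param channel which label channel to reconstruct (e.g. `"neuron"`).
#' @param cell_class class tag stored on each surface; defaults to
#'   `"<channel>_soma"`.
#' @param smooth_sigma_vox Gaussian sigma in voxels applied to the mask
#'   before iso-surfacing (0 disables smoothing).
#' @return list of `cell_surface` objects, each with `cell_id`,
#'   `cell_class`, `vertices`, `faces`, `centroid` (label mass centroid,
#'   um), `area` (um^2), `volume` (um^3), `truncated`, plus the voxel
#'   `mask`, `origin_um` and `voxel_size` it was built from.
#' @export
build_surfaces <- function(vol, channel = "neuron", cell_class = NULL,
                           smooth_sigma_vox = 1) {
  stopifnot(inherits(vol, "labeled_volume"))
  if (!channel %in% names(vol$labels)) {
    stopf("label channel '%s' not present (have: %s)", channel,
          paste(names(vol$labels), collapse = ", "))
  }
  lab <- vol$labels[[channel]]
  mx <- max(lab)
  ids <- if (mx < 1L) integer(0) else which(tabulate(lab, nbins = mx) > 0)
  cls <- cell_class %||% paste0(channel, "_soma")
  out <- list()
  for (id in ids) {
    mask <- lab == id
    s <- surface_from_mask(mask, vol$voxel_size, id, cls, smooth_sigma_vox)
    out[[length(out) + 1]] <- s
  }
  out
}

surface_from_mask <- function(mask, voxel_size, id, cls, smooth_sigma_vox) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(NULL)
  co <- arrayInd(idx, d)
  lo <- c(min(co[, 1]), min(co[, 2]), min(co[, 3]))
  hi <- c(max(co[, 1]), max(co[, 2]), max(co[, 3]))
  truncated <- any(lo == 1L) || any(hi == d)
  blo <- pmax(1L, lo - 1L); bhi <- pmin(d, hi + 1L)
  sub <- mask[blo[1]:bhi[1], blo[2]:bhi[2], blo[3]:bhi[3], drop = FALSE]
  origin <- (blo - 1L) * voxel_size
  m <- mesh_from_mask(sub, voxel_size, smooth_sigma_vox, origin_um = origin)
  if (is.null(m)) return(NULL)
  centroid <- (colMeans(co) - 0.5) * voxel_size
  fa <- mesh_face_areas(m$vertices, m$faces)
  structure(
    list(cell_id = id, cell_class = cls,
         vertices = m$vertices, faces = m$faces,
         centroid = centroid,
         area = sum(fa),
         volume = mesh_volume(m$vertices, m$faces),
         truncated = truncated,
         # closed by construction: iso-surface of a zero-padded field on a
         # globally consistent tetrahedral subdivision (verified in tests)
         closed = TRUE,
         mask = sub, origin_um = origin, voxel_size = voxel_size),
    class = "cell_surface")
}

#' @export
print.cell_surface <- function(x, ...) {
  cat(sprintf("<cell_surface> id=%s class=%s area=%.1f um^2 volume=%.1f um^3%s\n",
              x$cell_id, x$cell_class, x$area, x$volume,
              if (isTRUE(x$truncated)) " [truncated]" else ""))
  invisible(x)
}

#' Extract the microglial soma from a whole-cell surface
#'
#' Thin processes are removed by a morphological opening of the voxel mask
#' with a metric ball (default radius 1 um); the largest remaining
#' connected component is re-meshed as the soma. How the original analysis
#' separated soma from processes is not published; the opening radius is
#' our surrogate and is exposed for sensitivity analysis.
#'
#' @param surface a `cell_surface` (class `microglia_whole` or similar)
#'   carrying its voxel mask.
#' @param opening_radius_um radius of the opening ball; 0 returns the input
#'   geometry unchanged.
#' @return a `cell_surface` with `cell_class = "microglia_soma"`.
#' @export
extract_soma <- function(surface, opening_radius_um = 1.0) {
  stopifnot(inherits(surface, "cell_surface"))
  if (opening_radius_um <= 0) {
    out <- surface
    out$cell_class <- "microglia_soma"
    return(out)
  }
  opened <- open_mask(surface$mask, opening_radius_um, surface$voxel_size)
  if (!any(opened)) {
    stopf("opening with radius %.2f um erased cell %s entirely",
          opening_radius_um, surface$cell_id)
  }
  comp <- label_components(opened)
  sizes <- tabulate(comp[comp > 0])
  keep <- comp == which.max(sizes)
  out <- surface_from_mask(keep, surface$voxel_size, surface$cell_id,
                           "microglia_soma", smooth_sigma_vox = 1)
  # keep = bbox-relative mask; restore world origin
  out$vertices <- sweep(out$vertices, 2, surface$origin_um, "+")
  out$centroid <- out$centroid + surface$origin_um
  out$origin_um <- out$origin_um + surface$origin_um
  out$truncated <- surface$truncated
  out
}

#' Pair each microglia with its nearest neuron
#'
#' Exhaustive nearest-centroid assignment (ties broken towards the smaller
#' neuron id); truncated cells are excluded.
#'
#' @param neurons,microglia lists of `cell_surface` objects.
#' @return data.frame with `microglia_id`, `neuron_id`, `center_distance`
#'   (um).
#' @export
assign_pairs <- function(neurons, microglia) {
  neurons <- Filter(function(s) !isTRUE(s$truncated), neurons)
  microglia <- Filter(function(s) !isTRUE(s$truncated), microglia)
  if (!length(neurons) || !length(microglia)) {
    stopf("assign_pairs needs at least one untruncated neuron and microglia")
  }
  ncent <- t(vapply(neurons, function(s) s$centroid, numeric(3)))
  nid <- vapply(neurons, function(s) s$cell_id, numeric(1))
  rows <- lapply(microglia, function(m) {
    d <- sqrt(colSums((t(ncent) - m$centroid)^2))
    best <- min(d)
    cand <- which(d <= best + 1e-12)
    k <- cand[which.min(nid[cand])]
    data.frame(microglia_id = m$cell_id, neuron_id = nid[k],
               center_distance = d[k])
  })
  do.call(rbind, rows)
}
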