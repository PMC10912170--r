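#' Detect synaptic puncta in an intensity volume
#'
#' Scale-matched blob detection for VGAT-like presynaptic puncta with
#' target size 0.5 um in xy and 1 um in z: the volume is filtered with a
#' difference of anisotropic Gaussians tuned to that size, local maxima of
#' the response are collected, thresholded (Otsu on the positive response
#' by default) and refined to sub-voxel centres by a local
#' intensity-weighted centroid.
#'
#' @param intensity 3D numeric array (z, y, x).
#' @param voxel_size um per voxel (z, y, x).
#' @param diameter_xy,diameter_z expected punctum FWHM in um.
#' @param threshold response threshold; `NULL` uses Otsu.
#' @return data.frame with `id`, `z`, `y`, `x` (um) and `response`.
#' @export
detect_spots <- function(intensity, voxel_size, diameter_xy = 0.5,
                         diameter_z = 1, threshold = NULL) {
  if (any(voxel_size <= 0)) stopf("voxel_size must be positive")
  empty <- data.frame(id = integer(), z = numeric(), y = numeric(),
                      x = numeric(), response = numeric())
  if (all(intensity <= 0)) return(empty)
  sig <- c(diameter_z, diameter_xy, diameter_xy) / (2 * sqrt(2 * log(2)))
  g1 <- smooth_gaussian3d(intensity, sig, voxel_size)
  g2 <- smooth_gaussian3d(intensity, 1.6 * sig, voxel_size)
  resp <- g1 - g2
  mx <- local_maxima3d(resp)
  if (!any(mx)) return(empty)
  # threshold chosen on the response at candidate maxima: true puncta and
  # noise peaks form two well-separated modes there
  peak_vals <- resp[mx & resp > 0]
  if (!length(peak_vals)) return(empty)
  thr <- threshold %||% {
    r <- range(peak_vals)
    ot <- if (diff(r) < .Machine$double.eps) r[1] else
      EBImage::otsu(array((peak_vals - r[1]) / diff(r),
                          c(length(peak_vals), 1)),
                    range = c(0, 1)) * diff(r) + r[1]
    # never cut into the bright mode: Otsu on a handful of clean peaks can
    # land between genuine puncta of slightly different rendered intensity
    min(ot, 0.5 * max(peak_vals))
  }
  keep <- which(mx & resp >= thr)
  if (!length(keep)) return(empty)
  d <- dim(intensity)
  co <- arrayInd(keep, d)
  # sub-voxel refinement: centroid of the response over a 3x3x3 window
  centers <- t(vapply(seq_len(nrow(co)), function(i) {
    ci <- co[i, ]
    lo <- pmax(1L, ci - 1L); hi <- pmin(d, ci + 1L)
    w <- resp[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    w <- pmax(w, 0)
    g <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    if (sum(w) <= 0) return((ci - 0.5) * voxel_size)
    (colSums(g * as.vector(w)) / sum(w) - 0.5) * voxel_size
  }, numeric(3)))
  data.frame(id = seq_len(nrow(centers)), z = centers[, 1], y = centers[, 2],
             x = centers[, 3], response = resp[keep])
}

# strict local maxima over the 26-neighbourhood
local_maxima3d <- function(a) {
  d <- dim(a)
  pad <- array(-Inf, d + 2L)
  pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- a
  best <- array(-Inf, d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    nb <- pad[1 + dz + seq_len(d[1]), 1 + dy + seq_len(d[2]),
              1 + dx + seq_len(d[3])]
    best <- pmax(best, nb)
  }
  a > best
}

#' Classify puncta by signed distance to the paired cell surfaces
#'
#' Signed distances use the outward-normal convention (negative strictly
#' inside). Classes follow the precedence engulfed > on_microglia >
#' on_neuron > other: a punctum inside the microglial soma
#' (`dist_microglia < 0`) is engulfed and never also perisomatic; a
#' punctum within `band` um outside a surface is "on" that surface.
#' Distances are measured from the punctum centre.
#'
#' @param spots data.frame with um coordinates `z`, `y`, `x`.
#' @param neuron,microglia `cell_surface` objects (closed meshes).
#' @param band perisomatic distance band in um (default 0.5).
#' @return `spots` with `dist_neuron`, `dist_microglia`,
#'   `nearest_neuron_face` and `class` columns.
#' @export
classify_spots <- function(spots, neuron, microglia, band = 0.5) {
  if (band <= 0) stopf("band must be > 0")
  check_closed(neuron); check_closed(microglia)
  if (!nrow(spots)) {
    spots$dist_neuron <- numeric(0); spots$dist_microglia <- numeric(0)
    spots$nearest_neuron_face <- integer(0); spots$class <- character(0)
    return(spots)
  }
  p <- as.matrix(spots[, c("z", "y", "x")])
  dn <- signed_distance(p, neuron$vertices, neuron$faces)
  dm <- signed_distance(p, microglia$vertices, microglia$faces)
  spots$dist_neuron <- dn$distance
  spots$dist_microglia <- dm$distance
  spots$nearest_neuron_face <- dn$nearest_face
  cls <- rep("other", nrow(spots))
  on_n <- dn$distance >= 0 & dn$distance <= band
  on_m <- dm$distance >= 0 & dm$distance <= band
  cls[on_n] <- "on_neuron"
  cls[on_m] <- "on_microglia"          # precedence over on_neuron
  cls[dm$distance < 0] <- "engulfed"   # highest precedence
  spots$class <- cls
  spots
}

#' Tally classified puncta for one microglia-neuron pair
#'
#' Produces the per-pair counts of the displacement analysis: puncta on the
#' neuronal soma, on the microglial soma, engulfed, their pair total, and
#' the density of on-neuron puncta outside the contact patch (puncta whose
#' nearest neuron face is uncontacted, divided by the uncontacted area).
#'
#' @param spots classified spots from [classify_spots()].
#' @param patch result of [contact_patch()] for the same pair.
#' @return one-row data.frame with `n_on_neuron`, `n_on_microglia`,
#'   `n_engulfed`, `n_pair_total` and `density_outside_contact` (per um^2;
#'   `NA` when the contact patch covers the whole soma).
#' @export
tally_pair <- function(spots, patch) {
  n_on_neuron <- sum(spots$class == "on_neuron")
  n_on_microglia <- sum(spots$class == "on_microglia")
  n_engulfed <- sum(spots$class == "engulfed")
  area <- sum(patch$face_areas)
  free_area <- area - patch$contact_area
  if (free_area <= 0) {
    dens <- NA_real_
  } else {
    on_n <- spots$class == "on_neuron"
    outside <- on_n & !patch$face_contact[spots$nearest_neuron_face]
    dens <- sum(outside, na.rm = TRUE) / free_area
  }
  data.frame(n_on_neuron = n_on_neuron,
             n_on_microglia = n_on_microglia,
             n_engulfed = n_engulfed,
             n_pair_total = n_on_neuron + n_on_microglia,
             density_outside_contact = dens)
}

#' Read a pre-detected puncta table
#'
#' Accepts external spot coordinates (skipping [detect_spots()]); the CSV
#' must have columns `x`, `y`, `z` in micrometres (any order, extra
#' columns kept).
#'
#' @param path CSV file.
#' @return data.frame with at least `id`, `z`, `y`, `x`.
#' @export
read_spots_csv <- function(path) {
  df <- read.csv(path)
  need <- c("x", "y", "z")
  if (!all(need %in% names(df))) {
    stopf("spot table must have columns x, y, z (um); found: %s",
          paste(names(df), collapse = ", "))
  }
  if (!"id" %in% names(df)) df$id <- seq_len(nrow(df))
  df
}
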