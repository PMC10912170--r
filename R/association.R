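#' Microglia-neuron contact area and 3D surface coverage
#'
#' The contact patch is the set of neuron faces whose centroid lies within
#' `delta_contact` of the microglial mesh (points inside the microglia also
#' count as contact). Coverage is the contacted area divided by the total
#' neuronal soma area, the 3D analogue of "fraction of circumference
#' covered" in single-plane images.
#'
#' @param neuron,microglia `cell_surface` objects with closed meshes.
#' @param delta_contact contact distance threshold in um (default 0.2, one
#'   in-plane voxel).
#' @return list with `contact_area` (um^2), `coverage_3d` (fraction),
#'   `face_contact` (logical per neuron face) and `face_areas`.
#' @export
contact_patch <- function(neuron, microglia, delta_contact = 0.2) {
  if (delta_contact <= 0) stopf("delta_contact must be > 0")
  check_closed(neuron); check_closed(microglia)
  fc <- mesh_face_centroids(neuron$vertices, neuron$faces)
  fa <- mesh_face_areas(neuron$vertices, neuron$faces)
  contact <- cpp_contact_mask(fc, microglia$vertices, microglia$faces,
                              delta_contact)
  list(contact_area = sum(fa[contact]),
       coverage_3d = sum(fa[contact]) / sum(fa),
       face_contact = contact,
       face_areas = fa)
}

check_closed <- function(s) {
  closed <- s$closed %||% (mesh_boundary_edges(s$faces) == 0)
  if (!closed) {
    stopf("mesh for cell %s is not closed (has boundary edges)", s$cell_id)
  }
  invisible(TRUE)
}

#' Voxel-adjacency coverage oracle
#'
#' Brute-force, mesh-free measurement of 3D coverage used to validate the
#' mesh-based [contact_patch()]: the fraction of neuron boundary voxels
#' (6-neighbourhood) whose centre lies within `delta_contact` of the
#' microglial voxel mask, after allowing half an in-plane voxel for the
#' offset between voxel centres and the true cell boundary.
#'
#' @param neuron_mask,microglia_mask logical arrays on a common grid.
#' @param voxel_size um per voxel (z, y, x).
#' @param delta_contact contact threshold in um.
#' @return coverage fraction in `[0, 1]`.
#' @export
coverage_voxel_oracle <- function(neuron_mask, microglia_mask, voxel_size,
                                  delta_contact = 0.2) {
  stopifnot(identical(dim(neuron_mask), dim(microglia_mask)))
  nb <- boundary_voxels(neuron_mask)
  if (!any(nb)) return(NA_real_)
  if (!any(microglia_mask)) return(0)
  d <- distance_to_mask(microglia_mask, voxel_size)
  allow <- delta_contact + 0.5 * mean(voxel_size[2:3])
  sum(nb & d <= allow) / sum(nb)
}

# voxels of `mask` with at least one 6-neighbour outside the mask
boundary_voxels <- function(mask) {
  d <- dim(mask)
  m <- mask != 0
  pad <- array(FALSE, d + 2L)
  pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- m
  core <- pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])]
  nb_all <-
    pad[seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[2 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[1 + seq_len(d[1]), seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[1 + seq_len(d[1]), 2 + seq_len(d[2]), 1 + seq_len(d[3])] &
    pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), seq_len(d[3])] &
    pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 2 + seq_len(d[3])]
  core & !nb_all
}

#' 2D circumference coverage on the equatorial slice
#'
#' Fraction of the neuronal boundary arc length lying within
#' `delta_contact` of the microglial mask, measured on a single z-slice
#' (by convention the slice through the neuron centroid, matching
#' single-plane confocal analysis). The boundary is traced as the 0.5
#' iso-contour of the neuron mask; distances to the microglia are read
#' from an exact 2D distance transform with half a pixel allowed for the
#' centre-to-boundary offset.
#'
#' @param neuron_slice,microglia_slice logical/0-1 matrices (y, x).
#' @param voxel_size_yx um per pixel along (y, x).
#' @param delta_contact contact threshold in um.
#' @return fraction in `[0, 1]`.
#' @export
coverage_2d <- function(neuron_slice, microglia_slice, voxel_size_yx,
                        delta_contact = 0.2) {
  if (!any(neuron_slice != 0)) {
    stopf("neuron absent from the analysis slice")
  }
  if (!any(microglia_slice != 0)) return(0)
  ny <- nrow(neuron_slice); nx <- ncol(neuron_slice)
  ycoord <- (seq_len(ny) - 0.5) * voxel_size_yx[1]
  xcoord <- (seq_len(nx) - 0.5) * voxel_size_yx[2]
  cl <- grDevices::contourLines(ycoord, xcoord, (neuron_slice != 0) * 1.0,
                                levels = 0.5)
  if (!length(cl)) stopf("could not trace the neuron boundary contour")
  # largest closed contour = outer boundary
  len <- vapply(cl, function(p) sum(sqrt(diff(p$x)^2 + diff(p$y)^2)),
                numeric(1))
  p <- cl[[which.max(len)]]
  # 2D EDT of the microglia mask via the 3D kernel with a singleton z axis
  mg3 <- array(microglia_slice != 0, c(1L, ny, nx))
  dmg <- distance_to_mask(mg3, c(1, voxel_size_yx))[1, , ]
  seg_mid_y <- (head(p$x, -1) + tail(p$x, -1)) / 2  # contourLines: x=rows
  seg_mid_x <- (head(p$y, -1) + tail(p$y, -1)) / 2
  seg_len <- sqrt(diff(p$x)^2 + diff(p$y)^2)
  iy <- pmin(pmax(round(seg_mid_y / voxel_size_yx[1] + 0.5), 1), ny)
  ix <- pmin(pmax(round(seg_mid_x / voxel_size_yx[2] + 0.5), 1), nx)
  d <- dmg[cbind(iy, ix)]
  allow <- delta_contact + 0.5 * mean(voxel_size_yx)
  sum(seg_len[d <= allow]) / sum(seg_len)
}

#' Pixel-count oracle for 2D coverage
#'
#' Mesh/contour-free cross-check of [coverage_2d()]: the fraction of neuron
#' boundary pixels (4-neighbourhood) within `delta_contact` of the
#' microglia mask.
#'
#' @inheritParams coverage_2d
#' @export
coverage_2d_pixel_oracle <- function(neuron_slice, microglia_slice,
                                     voxel_size_yx, delta_contact = 0.2) {
  ny <- nrow(neuron_slice); nx <- ncol(neuron_slice)
  m <- neuron_slice != 0
  pad <- matrix(FALSE, ny + 2L, nx + 2L)
  pad[1 + seq_len(ny), 1 + seq_len(nx)] <- m
  nb_all <- pad[seq_len(ny), 1 + seq_len(nx)] &
    pad[2 + seq_len(ny), 1 + seq_len(nx)] &
    pad[1 + seq_len(ny), seq_len(nx)] &
    pad[1 + seq_len(ny), 2 + seq_len(nx)]
  nb <- m & !nb_all
  if (!any(nb)) return(NA_real_)
  if (!any(microglia_slice != 0)) return(0)
  mg3 <- array(microglia_slice != 0, c(1L, ny, nx))
  dmg <- distance_to_mask(mg3, c(1, voxel_size_yx))[1, , ]
  allow <- delta_contact + 0.5 * mean(voxel_size_yx)
  sum(nb & dmg <= allow) / sum(nb)
}

#' Fit the 2D-to-3D coverage calibration
#'
#' Ordinary least squares of 3D surface coverage (percent) on 2D
#' circumference coverage (percent) across cells analysed both ways. This
#' is the regression that converts the historical 25% circumference
#' criterion into a 3D surface threshold.
#'
#' @param coverage_2d_pct,coverage_3d_pct paired percent coverages.
#' @return list of class `calibration_model` with `slope`, `intercept`,
#'   `r2`, `n_cells`.
#' @export
fit_calibration <- function(coverage_2d_pct, coverage_3d_pct) {
  stopifnot(length(coverage_2d_pct) == length(coverage_3d_pct))
  if (length(coverage_2d_pct) < 3) stopf("calibration needs >= 3 cells")
  if (sd(coverage_2d_pct) < 1e-12) {
    stopf("degenerate calibration: 2D coverages have zero variance")
  }
  fit <- lm(coverage_3d_pct ~ coverage_2d_pct)
  sst <- sum((coverage_3d_pct - mean(coverage_3d_pct))^2)
  ssr <- sum(fit$residuals^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = if (sst <= 0) 0 else max(0, 1 - ssr / sst),
                 n_cells = length(coverage_2d_pct)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> Y = %.3f * X + %.3f (R^2 = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r2, x$n_cells))
  invisible(x)
}

#' Map a 2D circumference threshold to its 3D surface equivalent
#'
#' Evaluates the calibration regression at the 2D threshold and reports the
#' result to two decimals (the precision at which the derived threshold is
#' used for classification). With the published coefficients
#' (slope 0.545, intercept -0.355) the historical 25% circumference
#' criterion maps to 13.27% of the soma surface.
#'
#' @param model a `calibration_model` (or list with `slope`, `intercept`).
#' @param threshold_2d 2D threshold in percent (default 25).
#' @return 3D threshold in percent, rounded to two decimals.
#' @export
map_threshold <- function(model, threshold_2d = 25) {
  round(model$slope * threshold_2d + model$intercept, 2)
}

#' Classify extensive association and summarise by group
#'
#' Flags follow the field's thresholds exactly: extensive in 2D when the
#' covered circumference exceeds 25%, extensive in 3D when the covered
#' surface reaches 13.27% (the printed two-decimal threshold is treated as
#' inclusive). The summary percentage is
#' `100 * extensive / total` per `(region, animal)` cell; empty cells are
#' reported as missing, never as zero.
#'
#' @param records data.frame with at least `coverage_3d` (fraction) and
#'   optionally `coverage_2d`, `region`, `animal`.
#' @param threshold_2d,threshold_3d classification thresholds as fractions.
#' @return `records` with `extensive_2d`/`extensive_3d` flags, plus a
#'   `summary` attribute with the per-(region, animal) percentages when
#'   grouping columns are present.
#' @export
classify_association <- function(records, threshold_2d = 0.25,
                                 threshold_3d = 0.1327) {
  if (!nrow(records)) stopf("no association records")
  if ("coverage_2d" %in% names(records)) {
    records$extensive_2d <- records$coverage_2d > threshold_2d
  }
  records$extensive_3d <- records$coverage_3d >= threshold_3d
  keys <- intersect(c("region", "animal"), names(records))
  if (length(keys)) {
    agg <- aggregate(records$extensive_3d, by = records[keys],
                     FUN = function(z) 100 * mean(z))
    names(agg)[ncol(agg)] <- "pct_extensive"
    attr(records, "summary") <- agg
  }
  records
}
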