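#' Configuration for the synthetic tissue simulator
#'
#' The simulator emulates the statistical structure that the quantification
#' pipeline assumes: neuronal and microglial somata as mildly ellipsoidal
#' blobs on an anisotropic confocal grid (0.5 um z-step, 0.2 um in plane by
#' default), a controllable fraction of microglia planted in extensive
#' apposition to their nearest neuron at a prescribed surface coverage,
#' VGAT-like synaptic puncta scattered as a Poisson process on soma
#' surfaces, displacement of puncta that fall inside a contact patch
#' (relocated to the microglial soma surface, or suppressed), and a small
#' engulfed-puncta population strictly inside microglia.
#'
#' @param volume_shape integer length-3 `(nz, ny, nx)` or `NULL` to size the
#'   volume automatically from the packing requirements.
#' @param voxel_size um per voxel along (z, y, x).
#' @param n_neurons,n_microglia cell counts; each microglia is apposed to a
#'   distinct neuron, so `n_microglia <= n_neurons`.
#' @param neuron_radius_um,microglia_radius_um length-2 `(mean, sd)` of the
#'   soma radius in um.
#' @param p_assoc fraction of microglia planted as extensively associated.
#' @param coverage_assoc,coverage_nonassoc target fraction of the neuronal
#'   soma surface contacted for associated / non-associated pairs; the
#'   associated target must exceed the non-associated one, and straddling
#'   the 13.27% classification threshold is what makes recovery meaningful.
#' @param coverage_jitter half-width of the uniform jitter applied to the
#'   per-pair coverage target.
#' @param puncta_density expected puncta per um^2 of soma surface.
#' @param displacement_mode `"relocate"` moves puncta found inside the
#'   contact patch onto the free microglial surface (displacement, not
#'   loss); `"suppress"` deletes them.
#' @param displace_prob probability that a punctum inside the displacement
#'   zone is displaced.
#' @param displace_frac optional surface fraction of the displacement zone
#'   for associated pairs: a spherical cap centred on the contact axis
#'   covering this fraction of the neuronal surface. `NULL` (default)
#'   displaces only puncta lying inside the geometric contact patch;
#'   setting it larger than the planted coverage emulates displacement of
#'   synapses surrounding the contact, not just underneath it.
#' @param engulf_rate expected engulfed puncta per microglia (Poisson).
#' @param snr peak-signal-to-noise ratio of rendered intensity channels.
#' @param max_axis_ratio maximal ratio between ellipsoid semi-axes.
#' @param axis_tilt_max_deg maximal tilt of the neuron-to-microglia contact
#'   axis out of the xy plane (keeps the contact visible in the equatorial
#'   z-slice used by the 2D analysis, as in single-plane confocal fields).
#' @param n_processes number of thin tubular protrusions rendered per
#'   microglia (0 renders somata only).
#' @param delta_contact contact band in um used when planting coverage.
#' @param render if `FALSE`, skip rendering intensity channels (labels and
#'   ground truth only); used by large label-based recovery cohorts.
#' @param seed integer RNG seed; a fixed seed makes the volume and ground
#'   truth bit-reproducible.
#' @return a validated list of class `tissue_config`.
#' @export
tissue_config <- function(volume_shape = NULL,
                          voxel_size = c(0.5, 0.2, 0.2),
                          n_neurons = 4,
                          n_microglia = 3,
                          neuron_radius_um = c(5, 0.25),
                          microglia_radius_um = c(4.8, 0.25),
                          p_assoc = 0.3,
                          coverage_assoc = 0.22,
                          coverage_nonassoc = 0.04,
                          coverage_jitter = 0.02,
                          puncta_density = 0.15,
                          displacement_mode = c("relocate", "suppress"),
                          displace_prob = 1,
                          displace_frac = NULL,
                          engulf_rate = 2,
                          snr = 10,
                          max_axis_ratio = 1.15,
                          axis_tilt_max_deg = 30,
                          n_processes = 0,
                          delta_contact = 0.2,
                          render = TRUE,
                          seed = 1) {
  displacement_mode <- match.arg(displacement_mode)
  if (p_assoc < 0 || p_assoc > 1) stopf("p_assoc must lie in [0, 1]")
  if (coverage_nonassoc < 0) stopf("coverage_nonassoc must be >= 0")
  if (coverage_assoc <= coverage_nonassoc) {
    stopf("coverage_assoc (%.3f) must exceed coverage_nonassoc (%.3f)",
          coverage_assoc, coverage_nonassoc)
  }
  if (coverage_assoc >= 0.6) stopf("coverage_assoc must be < 0.6 (a soma cannot be majority-engulfed)")
  if (any(c(neuron_radius_um[1], microglia_radius_um[1], puncta_density) <= 0)) {
    stopf("radii and puncta_density must be > 0")
  }
  if (n_microglia > n_neurons) {
    stopf("n_microglia (%d) must not exceed n_neurons (%d): each microglia is apposed to a distinct neuron",
          n_microglia, n_neurons)
  }
  if (any(voxel_size <= 0)) stopf("voxel_size must be positive")
  if (max_axis_ratio < 1 || max_axis_ratio > 1.3) {
    stopf("max_axis_ratio must lie in [1, 1.3]")
  }
  if (!is.null(displace_frac) &&
      (displace_frac <= 0 || displace_frac >= 0.5)) {
    stopf("displace_frac must lie in (0, 0.5)")
  }
  cfg <- list(volume_shape = volume_shape, voxel_size = as.numeric(voxel_size),
              n_neurons = as.integer(n_neurons),
              n_microglia = as.integer(n_microglia),
              neuron_radius_um = neuron_radius_um,
              microglia_radius_um = microglia_radius_um,
              p_assoc = p_assoc, coverage_assoc = coverage_assoc,
              coverage_nonassoc = coverage_nonassoc,
              coverage_jitter = coverage_jitter,
              puncta_density = puncta_density,
              displacement_mode = displacement_mode,
              displace_prob = displace_prob,
              displace_frac = displace_frac,
              engulf_rate = engulf_rate, snr = snr,
              max_axis_ratio = max_axis_ratio,
              axis_tilt_max_deg = axis_tilt_max_deg,
              n_processes = as.integer(n_processes),
              delta_contact = delta_contact,
              render = isTRUE(render), seed = seed)
  class(cfg) <- "tissue_config"
  cfg
}

# --- ellipsoid primitives ---------------------------------------------------
# an ellipsoid is list(center, axes (semi-axes, um), rot (3x3)); all
# coordinates (z,y,x) um

# points n x 3 -> logical inside
ellipsoid_inside <- function(p, e, dilate = 0) {
  u <- sweep(p, 2, e$center) %*% e$rot
  u <- sweep(u, 2, e$axes + dilate, "/")
  rowSums(u^2) <= 1
}

ellipsoid_surface_points <- function(e, dirs) {
  s <- sweep(dirs, 2, e$axes, "*")
  sweep(s %*% t(e$rot), 2, e$center, "+")
}

# Knud Thomsen approximation of the ellipsoid surface area
ellipsoid_area <- function(axes) {
  p <- 1.6075
  a <- axes[1]; b <- axes[2]; c_ <- axes[3]
  4 * pi * (((a * b)^p + (a * c_)^p + (b * c_)^p) / 3)^(1 / p)
}

random_ellipsoid <- function(center, radius_mean, radius_sd, max_axis_ratio) {
  # radius draws truncated at +/- 1.5 sd so the cap-coverage feasibility
  # bound is met with bounded retries
  r <- radius_mean + radius_sd * max(-1.5, min(1.5, rnorm(1)))
  # mild random distortion with geometric-mean radius preserved
  lr <- runif(3, 0, log(max_axis_ratio))
  lr <- lr - mean(lr)
  list(center = center, axes = r * exp(lr), rot = random_rotation(),
       radius = r)
}

# fraction of the neuron surface (quasi-uniform sample) lying inside the
# microglia ellipsoid dilated by `delta`
.coverage_fraction <- function(neuron_pts, mg, delta = 0) {
  mean(ellipsoid_inside(neuron_pts, mg, dilate = delta))
}

# Solve the microglia centre distance along direction `u` that realizes the
# target coverage of the neuron surface. Returns the centre, or NULL if the
# target is infeasible for these shapes.
solve_contact_distance <- function(neuron, mg_axes, mg_rot, u, target,
                                   delta = 0.2, npts = 1200) {
  dirs <- fibonacci_sphere(npts)
  npts_surface <- ellipsoid_surface_points(neuron, dirs)
  cov_at <- function(d) {
    mg <- list(center = neuron$center + d * u, axes = mg_axes, rot = mg_rot)
    .coverage_fraction(npts_surface, mg, delta = delta)
  }
  d_hi <- max(neuron$axes) + max(mg_axes) + delta + 0.3
  d_lo <- max(0.25 * max(neuron$axes), max(neuron$axes) - max(mg_axes))
  grid <- seq(d_hi, d_lo, length.out = 18)
  cv <- vapply(grid, cov_at, numeric(1))
  k <- which(cv >= target)[1]           # first grid point past the target
  if (is.na(k) || k == 1) {
    if (is.na(k)) return(NULL)
    k <- 2
  }
  root <- uniroot(function(d) cov_at(d) - target,
                  lower = grid[k], upper = grid[k - 1], tol = 1e-3)
  d <- root$root
  list(center = neuron$center + d * u, distance = d,
       realized = cov_at(d))
}

# --- main entry -------------------------------------------------------------

#' Simulate a labelled tissue volume with planted ground truth
#'
#' Generates instance-label volumes for neuronal and microglial somata,
#' an intensity rendering per channel (unless `cfg$render` is `FALSE`),
#' and the complete ground truth needed to validate the downstream
#' pipeline: per-pair planted coverage and puncta bookkeeping, and
#' per-punctum true centres and hosts.
#'
#' In `"relocate"` mode the pre-displacement Poisson draw is conserved for
#' every pair (`puncta_on_neuron + puncta_relocated` equals the draw), so
#' the total puncta per pair is independent of the association flag by
#' construction.
#'
#' @param cfg a [tissue_config()].
#' @return list with elements `volume` ([labeled_volume()]), `ground_truth`
#'   (list of data.frames `pairs` and `puncta`), and `config`.
#' @export
simulate_volume <- function(cfg) {
  stopifnot(inherits(cfg, "tissue_config"))
  with_rng(cfg$seed, .simulate_volume_impl(cfg))
}

.simulate_volume_impl <- function(cfg) {
  vx <- cfg$voxel_size
  r_n <- cfg$neuron_radius_um[1]; r_m <- cfg$microglia_radius_um[1]
  tilt_max <- cfg$axis_tilt_max_deg * pi / 180
  single <- cfg$n_neurons == 1L
  # margin keeps every soma (and an apposed microglia) off the border
  margin <- 1.3 * r_n + 2.6 * r_m + 1
  if (is.null(cfg$volume_shape)) {
    if (single) {
      d_max <- 1.3 * (r_n + r_m)
      half_xy <- d_max + 1.3 * r_m + 0.8
      half_z <- max(1.3 * r_n, d_max * sin(tilt_max) + 1.3 * r_m) + 0.8
      shape <- ceiling(2 * c(half_z, half_xy, half_xy) / vx)
    } else {
      n_side <- ceiling(sqrt(cfg$n_neurons))
      pitch <- 2 * (1.3 * r_n + 1.3 * r_m) + 2
      ext_xy <- n_side * pitch + 2 * (margin - pitch / 2)
      ext_xy <- max(ext_xy, 2 * margin + 2)
      ext_z <- 2 * margin + 2
      shape <- ceiling(c(ext_z, ext_xy, ext_xy) / vx)
    }
  } else {
    shape <- as.integer(cfg$volume_shape)
  }
  extent <- shape * vx
  min_extent <- if (single) 2 * (1.3 * r_n + 0.6) else 2 * margin
  if (any(extent < min_extent)) {
    stopf("volume extent (%.1f x %.1f x %.1f um) too small: somata of radius %.1f um with apposed microglia need a %.1f um margin on every side",
          extent[1], extent[2], extent[3], r_n, min_extent / 2)
  }

  # ---- place neurons: single neuron centred; several neurons on a
  #      jittered xy grid with guaranteed separation ----
  neurons <- list()
  if (single) {
    neurons[[1]] <- random_ellipsoid(extent / 2, r_n,
                                     cfg$neuron_radius_um[2],
                                     cfg$max_axis_ratio)
  } else {
    pitch <- 2 * (1.3 * r_n + 1.3 * r_m) + 2
    nx_cells <- max(1L, floor((extent[3] - 2 * margin) / pitch) + 1L)
    ny_cells <- max(1L, floor((extent[2] - 2 * margin) / pitch) + 1L)
    if (nx_cells * ny_cells < cfg$n_neurons) {
      stopf("could not place %d neurons: volume fits only %d x %d soma sites of pitch %.1f um",
            cfg$n_neurons, ny_cells, nx_cells, pitch)
    }
    cells <- sample(nx_cells * ny_cells, cfg$n_neurons)
    jit <- pmax(0, (pitch - 2 * 1.3 * r_n - 2 * (1.3 * r_m + 0.6)) / 2)
    for (i in seq_len(cfg$n_neurons)) {
      cy <- (cells[i] - 1) %/% nx_cells
      cx <- (cells[i] - 1) %% nx_cells
      ctr <- c(runif(1, margin, extent[1] - margin),
               margin + cy * pitch + runif(1, -jit, jit),
               margin + cx * pitch + runif(1, -jit, jit))
      neurons[[i]] <- random_ellipsoid(ctr, r_n, cfg$neuron_radius_um[2],
                                       cfg$max_axis_ratio)
    }
  }

  # ---- place microglia apposed to distinct neurons ----
  host_ids <- sample.int(cfg$n_neurons, cfg$n_microglia)
  microglia <- list()
  pair_rows <- list()
  for (j in seq_len(cfg$n_microglia)) {
    ni <- host_ids[j]
    neuron <- neurons[[ni]]
    associated <- runif(1) < cfg$p_assoc
    target <- if (associated) cfg$coverage_assoc else cfg$coverage_nonassoc
    target <- if (target <= 0) 0 else
      max(0.005, target + runif(1, -cfg$coverage_jitter,
                                cfg$coverage_jitter))
    placed <- NULL
    for (attempt in 1:40) {
      mg_shape <- random_ellipsoid(c(0, 0, 0), r_m,
                                   cfg$microglia_radius_um[2],
                                   cfg$max_axis_ratio)
      tilt <- runif(1, -tilt_max, tilt_max)
      az <- runif(1, 0, 2 * pi)
      u <- c(sin(tilt), cos(tilt) * sin(az), cos(tilt) * cos(az))
      # discretization calibration: masks and meshes localize the realized
      # surface within the boundary voxel, so the effective rendered contact
      # band is ~3/4 of the nominal delta (see the methods vignette)
      plant_delta <- 0.75 * cfg$delta_contact
      if (target <= 0.004) {
        # explicit zero coverage: place just out of contact range
        sol <- solve_contact_distance(neuron, mg_shape$axes, mg_shape$rot,
                                      u, 0.01, delta = plant_delta)
        if (!is.null(sol)) {
          sol$center <- sol$center + 1.0 * u
          sol$distance <- sol$distance + 1.0
          sol$realized <- 0
        }
      } else {
        sol <- solve_contact_distance(neuron, mg_shape$axes, mg_shape$rot,
                                      u, target, delta = plant_delta)
      }
      if (is.null(sol)) next
      ctr <- sol$center
      if (any(ctr < max(mg_shape$axes) + 0.6) ||
          any(ctr > extent - max(mg_shape$axes) - 0.6)) next
      # avoid other cells
      clash <- FALSE
      for (k in seq_along(neurons)) {
        if (k == ni) next
        if (sqrt(sum((neurons[[k]]$center - ctr)^2)) <
            max(neurons[[k]]$axes) + max(mg_shape$axes) + 0.5) clash <- TRUE
      }
      for (k in seq_along(microglia)) {
        if (sqrt(sum((microglia[[k]]$center - ctr)^2)) <
            max(microglia[[k]]$axes) + max(mg_shape$axes) + 0.5) clash <- TRUE
      }
      if (clash) next
      placed <- list(center = ctr, axes = mg_shape$axes, rot = mg_shape$rot,
                     neuron_id = ni, associated = associated,
                     coverage = sol$realized, distance = sol$distance)
      break
    }
    if (is.null(placed)) {
      stopf("could not appose microglia %d to neuron %d at coverage %.3f (microglia radius %.2f um vs neuron radius %.2f um): coverage target infeasible or packing too tight",
            j, ni, target, r_m, max(neuron$axes))
    }
    microglia[[j]] <- placed
    pair_rows[[j]] <- data.frame(
      neuron_id = ni, microglia_id = j,
      associated = placed$associated,
      planted_coverage_3d = placed$coverage,
      planted_contact_area = placed$coverage * ellipsoid_area(neuron$axes),
      center_distance = placed$distance)
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(neuron_id = integer(), microglia_id = integer(),
               associated = logical(), planted_coverage_3d = numeric(),
               planted_contact_area = numeric(), center_distance = numeric())

  # ---- puncta: Poisson on each neuron surface, displaced inside contact ----
  mg_by_neuron <- integer(cfg$n_neurons)
  for (j in seq_along(microglia)) mg_by_neuron[microglia[[j]]$neuron_id] <- j
  punc <- list()
  pairs$puncta_total_draw <- 0L
  pairs$puncta_on_neuron <- 0L
  pairs$puncta_relocated <- 0L
  pairs$puncta_engulfed <- 0L
  outward <- function(p, center, offset = 0.15) {
    d <- sweep(p, 2, center)
    p + offset * d / sqrt(rowSums(d^2))
  }
  # relocation targets: points on the free microglial surface
  draw_on_mg <- function(mg, neuron, n) {
    out <- matrix(NA_real_, n, 3)
    need <- seq_len(n)
    for (t in 1:50) {
      if (!length(need)) break
      s <- ellipsoid_surface_points(mg, random_unit_vectors(length(need)))
      ok <- !ellipsoid_inside(s, neuron, dilate = 0.3)
      out[need[ok], ] <- s[ok, , drop = FALSE]
      need <- need[!ok]
    }
    if (length(need)) {
      # fall back to the anti-contact pole
      u <- mg$center - neuron$center
      u <- u / sqrt(sum(u^2))
      out[need, ] <- ellipsoid_surface_points(mg, matrix(u, length(need), 3,
                                                         byrow = TRUE))
    }
    outward(out, mg$center)
  }
  for (ni in seq_len(cfg$n_neurons)) {
    neuron <- neurons[[ni]]
    n_draw <- rpois(1, cfg$puncta_density * ellipsoid_area(neuron$axes))
    mgj <- mg_by_neuron[ni]
    mg <- if (mgj > 0) microglia[[mgj]] else NULL
    n_kept <- 0L; n_reloc <- 0L
    if (n_draw > 0) {
      pts <- ellipsoid_surface_points(neuron, random_unit_vectors(n_draw))
      in_patch <- if (is.null(mg)) rep(FALSE, n_draw) else
        ellipsoid_inside(pts, mg, dilate = cfg$delta_contact)
      in_zone <- in_patch
      if (!is.null(cfg$displace_frac) && !is.null(mg) && mg$associated) {
        u_axis <- mg$center - neuron$center
        u_axis <- u_axis / sqrt(sum(u_axis^2))
        dw <- sweep(pts, 2, neuron$center)
        dw <- dw / sqrt(rowSums(dw^2))
        in_zone <- in_patch | (c(dw %*% u_axis) >= 1 - 2 * cfg$displace_frac)
      }
      displaced <- in_zone & (runif(n_draw) < cfg$displace_prob)
      kept_pts <- outward(pts[!displaced, , drop = FALSE], neuron$center)
      n_kept <- nrow(kept_pts)
      reloc_pts <- NULL
      if (cfg$displacement_mode == "relocate" && any(displaced)) {
        reloc_pts <- draw_on_mg(mg, neuron, sum(displaced))
        n_reloc <- nrow(reloc_pts)
      }
      if (n_kept > 0) {
        punc[[length(punc) + 1]] <- data.frame(
          z = kept_pts[, 1], y = kept_pts[, 2], x = kept_pts[, 3],
          host = "neuron_surface", neuron_id = ni,
          microglia_id = ifelse(mgj > 0, mgj, NA_integer_))
      }
      if (n_reloc > 0) {
        punc[[length(punc) + 1]] <- data.frame(
          z = reloc_pts[, 1], y = reloc_pts[, 2], x = reloc_pts[, 3],
          host = "microglia_surface", neuron_id = ni, microglia_id = mgj)
      }
    }
    if (mgj > 0) {
      k <- which(pairs$microglia_id == mgj)
      pairs$puncta_total_draw[k] <- n_draw
      pairs$puncta_on_neuron[k] <- n_kept
      pairs$puncta_relocated[k] <- n_reloc
    }
  }
  # engulfed puncta strictly inside each microglia (outside any neuron)
  for (j in seq_along(microglia)) {
    mg <- microglia[[j]]
    n_e <- rpois(1, cfg$engulf_rate)
    neuron <- neurons[[mg$neuron_id]]
    if (n_e > 0) {
      s <- matrix(NA_real_, n_e, 3)
      need <- seq_len(n_e)
      for (t in 1:50) {
        if (!length(need)) break
        u <- random_unit_vectors(length(need)) * runif(length(need), 0.25, 0.55)
        cand <- sweep(sweep(u, 2, mg$axes, "*") %*% t(mg$rot), 2,
                      mg$center, "+")
        ok <- !ellipsoid_inside(cand, neuron, dilate = 0.3)
        s[need[ok], ] <- cand[ok, , drop = FALSE]
        need <- need[!ok]
      }
      if (length(need)) {
        u <- mg$center - neuron$center
        u <- 0.4 * u / sqrt(sum(u^2))
        s[need, ] <- matrix(mg$center + u * min(mg$axes), length(need), 3,
                            byrow = TRUE)
      }
      punc[[length(punc) + 1]] <- data.frame(
        z = s[, 1], y = s[, 2], x = s[, 3], host = "microglia_interior",
        neuron_id = mg$neuron_id, microglia_id = j)
    }
    k <- which(pairs$microglia_id == j)
    pairs$puncta_engulfed[k] <- n_e
  }
  puncta <- if (length(punc)) do.call(rbind, punc) else
    data.frame(z = numeric(), y = numeric(), x = numeric(),
               host = character(), neuron_id = integer(),
               microglia_id = integer())
  puncta <- cbind(id = seq_len(nrow(puncta)), puncta)
  rownames(puncta) <- NULL

  # ---- voxelize labels ----
  lab_n <- array(0L, shape)
  lab_m <- array(0L, shape)
  fill_ellipsoid <- function(lab, e, id, exclude = NULL) {
    lo <- pmax(1L, floor((e$center - max(e$axes) - 0.5) / vx))
    hi <- pmin(shape, ceiling((e$center + max(e$axes) + 0.5) / vx))
    g <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    p <- sweep(g - 0.5, 2, vx, "*")
    inside <- ellipsoid_inside(p, e)
    if (!is.null(exclude)) {
      for (ex in exclude) inside <- inside & !ellipsoid_inside(p, ex)
    }
    idx <- g[inside, , drop = FALSE]
    lab[idx] <- id
    lab
  }
  for (ni in seq_len(cfg$n_neurons)) {
    lab_n <- fill_ellipsoid(lab_n, neurons[[ni]], ni)
  }
  for (j in seq_along(microglia)) {
    mg <- microglia[[j]]
    # separate channels: neuron and microglia masks may overlap, as the
    # two stains do in a real acquisition
    lab_m <- fill_ellipsoid(lab_m, mg, j)
    if (cfg$n_processes > 0) {
      lab_m <- add_processes(lab_m, mg, j, cfg$n_processes, vx, shape,
                             exclude = neurons[[mg$neuron_id]])
    }
  }

  channels <- list()
  if (cfg$render) {
    noise_sd <- 1 / cfg$snr
    channels$neuron <- smooth_gaussian3d((lab_n > 0) * 1.0, c(0.3, 0.15, 0.15), vx) +
      array(rnorm(prod(shape), 0, noise_sd), shape)
    channels$microglia <- smooth_gaussian3d((lab_m > 0) * 1.0, c(0.3, 0.15, 0.15), vx) +
      array(rnorm(prod(shape), 0, noise_sd), shape)
    channels$puncta <- render_puncta(puncta, shape, vx) +
      array(rnorm(prod(shape), 0, noise_sd), shape)
  }

  vol <- labeled_volume(list(neuron = lab_n, microglia = lab_m), vx, channels)
  list(volume = vol,
       ground_truth = list(pairs = pairs, puncta = puncta),
       config = cfg,
       geometry = list(neurons = neurons, microglia = microglia))
}

# thin tubular protrusions rendered as capsules from the soma surface
add_processes <- function(lab, mg, id, n, vx, shape, exclude,
                          radius = 0.3, len_range = c(3, 7)) {
  for (k in seq_len(n)) {
    dir <- random_unit_vectors(1)[1, ]
    base <- ellipsoid_surface_points(mg, matrix(dir, 1))[1, ]
    len <- runif(1, len_range[1], len_range[2])
    tip <- base + dir * len
    lo <- pmax(1L, floor((pmin(base, tip) - radius - 0.5) / vx))
    hi <- pmin(shape, ceiling((pmax(base, tip) + radius + 0.5) / vx))
    if (any(lo > hi)) next
    g <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    p <- sweep(g - 0.5, 2, vx, "*")
    ap <- sweep(p, 2, base)
    t_ <- pmin(pmax(ap %*% dir, 0), len)
    d2 <- rowSums((ap - t_ %*% t(dir))^2)
    inside <- d2 <= radius^2 & !ellipsoid_inside(p, exclude)
    idx <- g[inside, , drop = FALSE]
    lab[idx] <- id
  }
  lab
}

# rendered puncta: anisotropic Gaussian spots, FWHM 0.5 um (xy) / 1 um (z)
render_puncta <- function(puncta, shape, vx, fwhm = c(1, 0.5, 0.5),
                          amplitude = 1) {
  vol <- array(0, shape)
  if (!nrow(puncta)) return(vol)
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  half <- ceiling(3 * sig / vx)
  for (q in seq_len(nrow(puncta))) {
    ctr <- c(puncta$z[q], puncta$y[q], puncta$x[q])
    ci <- pmin(pmax(round(ctr / vx + 0.5), 1), shape)
    lo <- pmax(1L, ci - half)
    hi <- pmin(shape, ci + half)
    iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
    gz <- exp(-((iz - 0.5) * vx[1] - ctr[1])^2 / (2 * sig[1]^2))
    gy <- exp(-((iy - 0.5) * vx[2] - ctr[2])^2 / (2 * sig[2]^2))
    gx <- exp(-((ix - 0.5) * vx[3] - ctr[3])^2 / (2 * sig[3]^2))
    vol[iz, iy, ix] <- vol[iz, iy, ix] +
      amplitude * outer(outer(gz, gy), gx)
  }
  dim(vol) <- shape
  vol
}
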