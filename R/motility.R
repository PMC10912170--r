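#' Simulate co-culture microglial trajectories around a neuron soma
#'
#' 2D drift-diffusion walks around a circular neuronal soma at the origin.
#' Each step combines an isotropic diffusive component with a radial drift
#' towards the soma; both are scaled by a distance-dependent speed factor
#' `1 + speed_gain * r / (r + d)` (d = distance to the soma boundary), so
#' locomotion accelerates as microglia close in when `speed_gain > 0`.
#' Negative `drift` biases movement away from the soma.
#'
#' @param n_microglia number of tracks.
#' @param drift signed radial drift in um/min (positive = towards soma).
#' @param speed_gain unitless gain of the distance-dependent acceleration.
#' @param duration,dt total time and frame interval in minutes.
#' @param seed RNG seed.
#' @param neuron_radius soma radius in um.
#' @param sigma diffusive step scale in um/sqrt(min).
#' @param init_range initial boundary distances are drawn uniformly from
#'   this range (um).
#' @return list with `tracks` (data.frame `microglia_id`, `t_min`, `y_um`,
#'   `x_um`, `distance_um` to the soma boundary) and `neuron`
#'   (list `center`, `radius`).
#' @export
simulate_coculture_tracks <- function(n_microglia, drift = 0,
                                      speed_gain = 0, duration = 60,
                                      dt = 1, seed = 1,
                                      neuron_radius = 10, sigma = 2,
                                      init_range = c(10, 50)) {
  if (dt <= 0) stopf("dt must be > 0")
  if (duration < dt) stopf("duration must be >= dt")
  with_rng(seed, {
    times <- seq(0, duration, by = dt)
    rows <- vector("list", n_microglia)
    for (i in seq_len(n_microglia)) {
      d0 <- runif(1, init_range[1], init_range[2])
      ang <- runif(1, 0, 2 * pi)
      p <- (neuron_radius + d0) * c(sin(ang), cos(ang))
      ys <- xs <- numeric(length(times))
      ys[1] <- p[1]; xs[1] <- p[2]
      arrived <- FALSE
      for (k in seq_along(times)[-1]) {
        dist <- max(sqrt(sum(p^2)) - neuron_radius, 0)
        if (!arrived) {
          mult <- 1 + speed_gain * neuron_radius / (neuron_radius + dist)
          u <- -p / max(sqrt(sum(p^2)), 1e-9)   # towards the soma
          p <- p + mult * (drift * dt * u + sigma * sqrt(dt) * rnorm(2))
          r <- sqrt(sum(p^2))
          if (r <= neuron_radius) {
            p <- p * neuron_radius / max(r, 1e-9)
            arrived <- TRUE   # contact made: the microglia settles
          }
        }
        ys[k] <- p[1]; xs[k] <- p[2]
      }
      rows[[i]] <- data.frame(microglia_id = i, t_min = times,
                              y_um = ys, x_um = xs,
                              distance_um = pmax(sqrt(ys^2 + xs^2) -
                                                   neuron_radius, 0))
    }
    list(tracks = do.call(rbind, rows),
         neuron = list(center = c(0, 0), radius = neuron_radius))
  })
}

#' Classify per-interval movement towards/away from the neuron
#'
#' For each frame interval: `+1` if the boundary distance decreased by more
#' than `epsilon`, `-1` if it increased by more than `epsilon`, else `0`
#' (immobile).
#'
#' @param track data.frame for one microglia with `t_min` and
#'   `distance_um`.
#' @param epsilon immobility threshold in um per interval.
#' @return data.frame with `t_start`, `t_end`, `class`, `speed_um_min`
#'   (positive = approaching) and `start_distance_um`.
#' @export
classify_movement <- function(track, epsilon = 1.0) {
  if (nrow(track) < 2) stopf("track needs >= 2 frames")
  if (epsilon < 0) stopf("epsilon must be >= 0")
  o <- order(track$t_min)
  track <- track[o, ]
  dt <- diff(track$t_min)
  if (any(dt <= 0)) stopf("timestamps must be strictly increasing")
  dd <- diff(track$distance_um)
  cls <- integer(length(dd))
  cls[dd < -epsilon] <- 1L
  cls[dd > epsilon] <- -1L
  data.frame(t_start = head(track$t_min, -1), t_end = tail(track$t_min, -1),
             class = cls, speed_um_min = -dd / dt,
             start_distance_um = head(track$distance_um, -1),
             end_distance_um = tail(track$distance_um, -1))
}

#' Association index of a microglial cohort at a time point
#'
#' Sum over microglia of the movement class (+1 towards, 0 immobile, -1
#' away) of the interval starting at time `t`; bounded by the number of
#' tracks. Tracks without that interval are excluded with a warning.
#'
#' @param tracks data.frame of all tracks (`microglia_id`, `t_min`,
#'   `distance_um`).
#' @param t interval start time (min).
#' @param epsilon immobility threshold passed to [classify_movement()].
#' @return integer index.
#' @export
association_index <- function(tracks, t, epsilon = 1.0) {
  ids <- unique(tracks$microglia_id)
  total <- 0L
  missing <- 0L
  for (id in ids) {
    cl <- classify_movement(tracks[tracks$microglia_id == id, ], epsilon)
    k <- which(abs(cl$t_start - t) < 1e-9)
    if (!length(k)) { missing <- missing + 1L; next }
    total <- total + cl$class[k[1]]
  }
  if (missing > 0) {
    warning(sprintf("%d track(s) do not cover t = %g and were excluded",
                    missing, t))
  }
  total
}

#' Association-index time series
#'
#' @inheritParams association_index
#' @return data.frame `t_start`, `index`, `n_towards`, `n_away`,
#'   `n_immobile`.
#' @export
association_index_series <- function(tracks, epsilon = 1.0) {
  ids <- unique(tracks$microglia_id)
  cls <- do.call(rbind, lapply(ids, function(id) {
    classify_movement(tracks[tracks$microglia_id == id, ], epsilon)
  }))
  agg <- aggregate(cls$class, by = list(t_start = cls$t_start),
                   FUN = function(z) c(index = sum(z),
                                       towards = sum(z == 1),
                                       away = sum(z == -1),
                                       immobile = sum(z == 0)))
  data.frame(t_start = agg$t_start, index = agg$x[, "index"],
             n_towards = agg$x[, "towards"], n_away = agg$x[, "away"],
             n_immobile = agg$x[, "immobile"])
}

#' Mean approach speed binned by distance in folds of the soma radius
#'
#' Only approach intervals (class +1) contribute, and intervals that end
#' in soma contact (distance 0) are excluded: their displacement is
#' truncated by arrival, so they measure the remaining gap rather than
#' locomotion speed. Each remaining interval is binned by its starting
#' distance from the soma centre expressed in multiples of the soma
#' radius; the bin speed is the mean of `-d(distance)/dt`. Empty bins are
#' reported as `NA`, never 0.
#'
#' @param tracks data.frame of all tracks.
#' @param neuron_radius soma radius r in um.
#' @param fold_edges increasing bin edges in multiples of r (default 1:5,
#'   i.e. annuli `[1r,2r) ... [4r,5r)`).
#' @param epsilon immobility threshold.
#' @return data.frame `fold_lo`, `fold_hi`, `mean_speed_um_min`,
#'   `n_intervals`.
#' @export
speed_by_radius_fold <- function(tracks, neuron_radius,
                                 fold_edges = 1:5, epsilon = 1.0) {
  if (length(fold_edges) < 2 || any(diff(fold_edges) <= 0)) {
    stopf("fold_edges must be >= 2 increasing values")
  }
  ids <- unique(tracks$microglia_id)
  cls <- do.call(rbind, lapply(ids, function(id) {
    classify_movement(tracks[tracks$microglia_id == id, ], epsilon)
  }))
  appr <- cls[cls$class == 1L & cls$end_distance_um > 0, ]
  folds <- (appr$start_distance_um + neuron_radius) / neuron_radius
  bin <- cut(folds, fold_edges, right = FALSE)
  out <- data.frame(fold_lo = head(fold_edges, -1),
                    fold_hi = tail(fold_edges, -1))
  out$mean_speed_um_min <- NA_real_
  out$n_intervals <- 0L
  if (nrow(appr)) {
    m <- tapply(appr$speed_um_min, bin, mean)
    n <- tapply(appr$speed_um_min, bin, length)
    out$mean_speed_um_min <- as.numeric(m)
    out$n_intervals <- ifelse(is.na(n), 0L, as.integer(n))
  }
  out
}
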