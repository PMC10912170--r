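#' Analyse one labelled volume end to end
#'
#' Runs the geometry pipeline on a (simulated or externally segmented)
#' [labeled_volume()]: surfaces for both channels, nearest-neuron pairing,
#' contact/coverage per pair, puncta classification and per-pair tallies.
#' Puncta coordinates are either supplied (e.g. the simulator ground truth
#' or an external spot table) or detected from the `puncta` intensity
#' channel. Each spot is evaluated only against its pair (the nearest
#' neuron to the spot, and that neuron's microglia).
#'
#' @param vol a [labeled_volume()].
#' @param spots data.frame with um coordinates `z`, `y`, `x`, or `NULL` to
#'   run [detect_spots()] on the `puncta` intensity channel.
#' @param delta_contact contact band in um.
#' @param band perisomatic distance band in um.
#' @param threshold_3d extensive-association threshold (fraction).
#' @param smooth_sigma_vox mask smoothing for surface extraction.
#' @param fast use the accelerated distance queries (identical
#'   definitions; exact winding-number distances otherwise).
#' @return data.frame, one row per microglia-neuron pair: ids, coverage,
#'   contact area, extensive flag and puncta tallies.
#' @export
analyze_volume <- function(vol, spots = NULL, delta_contact = 0.2,
                           band = 0.5, threshold_3d = 0.1327,
                           smooth_sigma_vox = 1, fast = TRUE) {
  neurons <- build_surfaces(vol, "neuron", cell_class = "neuron_soma",
                            smooth_sigma_vox = smooth_sigma_vox)
  microglia <- build_surfaces(vol, "microglia", cell_class = "microglia_soma",
                              smooth_sigma_vox = smooth_sigma_vox)
  pairs <- assign_pairs(neurons, microglia)
  if (is.null(spots)) {
    if (!"puncta" %in% names(vol$channels)) {
      stopf("no spot table given and no 'puncta' intensity channel to detect from")
    }
    spots <- detect_spots(vol$channels$puncta, vol$voxel_size)
  }
  nid <- vapply(neurons, function(s) s$cell_id, numeric(1))
  mid <- vapply(microglia, function(s) s$cell_id, numeric(1))
  # spot -> nearest neuron assignment
  spot_neuron <- if (nrow(spots)) {
    ncent <- t(vapply(neurons, function(s) s$centroid, numeric(3)))
    p <- as.matrix(spots[, c("z", "y", "x")])
    apply(p, 1, function(q) nid[which.min(colSums((t(ncent) - q)^2))])
  } else numeric(0)
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    neuron <- neurons[[match(pairs$neuron_id[k], nid)]]
    mg <- microglia[[match(pairs$microglia_id[k], mid)]]
    patch <- contact_patch(neuron, mg, delta_contact)
    sp <- spots[spot_neuron == pairs$neuron_id[k], , drop = FALSE]
    cls <- classify_spots_impl(sp, neuron, mg, band, fast = fast)
    tly <- tally_pair(cls, patch)
    cbind(pairs[k, , drop = FALSE],
          data.frame(coverage_3d = patch$coverage_3d,
                     contact_area = patch$contact_area,
                     neuron_area = neuron$area,
                     extensive_3d = patch$coverage_3d >= threshold_3d),
          tly)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# classify with a choice of distance backend; the fast backend signs by
# the nearest-face normal instead of the winding number
classify_spots_impl <- function(spots, neuron, microglia, band, fast = TRUE) {
  if (!fast) return(classify_spots(spots, neuron, microglia, band))
  if (!nrow(spots)) {
    spots$dist_neuron <- numeric(0); spots$dist_microglia <- numeric(0)
    spots$nearest_neuron_face <- integer(0); spots$class <- character(0)
    return(spots)
  }
  p <- as.matrix(spots[, c("z", "y", "x")])
  dn <- cpp_signed_distance_fast(p, neuron$vertices, neuron$faces)
  dm <- cpp_signed_distance_fast(p, microglia$vertices, microglia$faces)
  spots$dist_neuron <- dn$distance
  spots$dist_microglia <- dm$distance
  spots$nearest_neuron_face <- dn$nearest_face
  cls <- rep("other", nrow(spots))
  cls[dn$distance >= 0 & dn$distance <= band] <- "on_neuron"
  cls[dm$distance >= 0 & dm$distance <= band] <- "on_microglia"
  cls[dm$distance < 0] <- "engulfed"
  spots$class <- cls
  spots
}

#' Simulate and analyse a cohort of microglia-neuron pairs
#'
#' The desk-scale surrogate of a multi-animal imaging experiment: each
#' pair is simulated as its own small field (one neuron, one microglia,
#' labels only) and pushed through the full geometry pipeline. Per-pair
#' ground truth and measurements are returned side by side.
#'
#' @param n_animals,pairs_per_animal cohort design.
#' @param seed master seed; per-pair seeds are derived deterministically.
#' @param voxel_size um per voxel used for the cohort fields (coarser than
#'   single-field analyses to keep cohorts desk-scale).
#' @param delta_contact,band analysis parameters.
#' @param ... overrides passed to [tissue_config()] (e.g. `p_assoc`,
#'   `coverage_assoc`, `engulf_rate`).
#' @return data.frame with one row per pair: `animal`, planted truth
#'   columns and measured columns.
#' @export
simulate_pair_cohort <- function(n_animals = 5, pairs_per_animal = 100,
                                 seed = 1, voxel_size = c(0.5, 0.5, 0.5),
                                 delta_contact = 0.2, band = 0.5, ...) {
  rows <- vector("list", n_animals * pairs_per_animal)
  k <- 0
  for (a in seq_len(n_animals)) {
    for (j in seq_len(pairs_per_animal)) {
      pair_seed <- (as.numeric(seed) * 7919 + a * 100003 + j * 101) %%
        2147483647
      cfg <- tissue_config(n_neurons = 1, n_microglia = 1, render = FALSE,
                           voxel_size = voxel_size, seed = pair_seed, ...)
      sim <- simulate_volume(cfg)
      res <- analyze_volume(sim$volume, spots = sim$ground_truth$puncta,
                            delta_contact = delta_contact, band = band,
                            fast = TRUE)
      truth <- sim$ground_truth$pairs
      k <- k + 1
      rows[[k]] <- data.frame(
        animal = a, pair = j,
        planted_associated = truth$associated,
        planted_coverage_3d = truth$planted_coverage_3d,
        planted_total_draw = truth$puncta_total_draw,
        planted_on_neuron = truth$puncta_on_neuron,
        planted_relocated = truth$puncta_relocated,
        planted_engulfed = truth$puncta_engulfed,
        coverage_3d = res$coverage_3d,
        extensive_3d = res$extensive_3d,
        n_on_neuron = res$n_on_neuron,
        n_on_microglia = res$n_on_microglia,
        n_engulfed = res$n_engulfed,
        n_pair_total = res$n_pair_total,
        density_outside_contact = res$density_outside_contact)
    }
  }
  do.call(rbind, rows)
}

# long-format export of a cohort for the clustered comparisons
cohort_long <- function(cohort, measure) {
  data.frame(animal_id = cohort$animal,
             group = ifelse(cohort$extensive_3d, "associated",
                            "non_associated"),
             value = cohort[[measure]])
}

#' Run the full pipeline from a configuration
#'
#' Simulates a cohort, classifies association, tallies puncta, runs the
#' animal-clustered comparisons, and writes per-pair and summary CSVs, a
#' results JSON and a run manifest into `out_dir`.
#'
#' Required configuration keys (YAML file or list): `seed`, `n_animals`,
#' `pairs_per_animal`; optional: `tissue` (overrides for
#' [tissue_config()]), `delta_contact`, `band`, `n_boot`, `voxel_size`.
#'
#' @param config path to a YAML file or a named list.
#' @param out_dir output directory.
#' @return invisibly, the comparison results list.
#' @export
run_full <- function(config, out_dir) {
  cfg_file <- NULL
  if (is.character(config)) {
    cfg_file <- config
    config <- yaml::read_yaml(config)
  }
  for (key in c("seed", "n_animals", "pairs_per_animal")) {
    if (is.null(config[[key]])) stopf("config key '%s' is missing", key)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cfg_file)) {
    cfg_file <- file.path(out_dir, "config.yaml")
    yaml::write_yaml(config, cfg_file)
  }
  delta <- config$delta_contact %||% 0.2
  band <- config$band %||% 0.5
  n_boot <- config$n_boot %||% 2000
  vs <- config$voxel_size %||% c(0.5, 0.5, 0.5)
  tissue <- config$tissue %||% list()
  cohort <- do.call(simulate_pair_cohort,
                    c(list(n_animals = config$n_animals,
                           pairs_per_animal = config$pairs_per_animal,
                           seed = config$seed, voxel_size = vs,
                           delta_contact = delta, band = band), tissue))
  pair_csv <- file.path(out_dir, "pairs.csv")
  write.csv(cohort, pair_csv, row.names = FALSE)

  prop <- proportion_summary(data.frame(extensive = cohort$extensive_3d,
                                        animal_id = cohort$animal))
  prop_csv <- file.path(out_dir, "association_summary.csv")
  write.csv(prop$per_animal, prop_csv, row.names = FALSE)

  comparisons <- lapply(
    c(n_on_neuron = "n_on_neuron", n_on_microglia = "n_on_microglia",
      n_pair_total = "n_pair_total", n_engulfed = "n_engulfed"),
    function(m) {
      s <- cohort_long(cohort, m)
      if (length(unique(s$animal_id[s$group == "associated"])) < 2 ||
          length(unique(s$animal_id[s$group == "non_associated"])) < 2) {
        return(NULL)
      }
      cluster_bootstrap_diff(s, "associated", "non_associated",
                             n_boot = n_boot, seed = config$seed)
    })
  res_json <- file.path(out_dir, "comparisons.json")
  jsonlite::write_json(comparisons, res_json, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  manifest <- write_manifest(out_dir, cfg_file, config$seed,
                             params = list(delta_contact = delta,
                                           band = band, n_boot = n_boot,
                                           voxel_size = vs),
                             outputs = c(pair_csv, prop_csv, res_json))
  invisible(list(cohort = cohort, proportions = prop,
                 comparisons = comparisons, manifest = manifest))
}

#' Run the recovery suite: property checks against planted ground truth
#'
#' A compact battery of the pipeline's core recovery properties on a
#' freshly simulated cohort: coverage recovery, puncta conservation, the
#' displacement signature (sign of the on-neuron deficit and on-microglia
#' surplus), the engulfment null, motility shape and gamma-power recovery.
#'
#' @param config named list; recognised keys `seed`, `n_animals`,
#'   `pairs_per_animal`, `tissue` (all optional).
#' @return data.frame with one row per check: `check`, `value`, `pass`,
#'   `note`.
#' @export
run_recovery_suite <- function(config = list()) {
  seed <- config$seed %||% 1
  n_animals <- config$n_animals %||% 2
  ppa <- config$pairs_per_animal %||% 15
  tissue <- config$tissue %||% list()
  cohort <- do.call(simulate_pair_cohort,
                    c(list(n_animals = n_animals, pairs_per_animal = ppa,
                           seed = seed), tissue))
  checks <- list()
  add <- function(check, value, pass, note = "") {
    checks[[length(checks) + 1]] <<- data.frame(check = check, value = value,
                                                pass = pass, note = note)
  }
  cov_err <- max(abs(cohort$coverage_3d - cohort$planted_coverage_3d))
  add("coverage_recovery_max_abs_error", cov_err, cov_err <= 0.05)
  cons <- max(abs(cohort$n_pair_total - cohort$planted_total_draw))
  add("puncta_conservation_max_abs_error", cons, cons <= 1)
  if (any(cohort$planted_associated) && any(!cohort$planted_associated)) {
    d_on <- mean(cohort$n_on_neuron[cohort$extensive_3d]) -
      mean(cohort$n_on_neuron[!cohort$extensive_3d])
    add("on_neuron_deficit", d_on, d_on < 0)
    d_mg <- mean(cohort$n_on_microglia[cohort$extensive_3d]) -
      mean(cohort$n_on_microglia[!cohort$extensive_3d])
    add("on_microglia_surplus", d_mg, d_mg > 0)
    d_tot <- abs(mean(cohort$n_pair_total[cohort$extensive_3d]) /
                   mean(cohort$n_pair_total[!cohort$extensive_3d]) - 1)
    add("pair_total_relative_difference", d_tot, d_tot < 0.05)
  } else {
    add("on_neuron_deficit", NA, NA, "not applicable: cohort has a single association class")
  }
  tr <- simulate_coculture_tracks(60, drift = 1.2, speed_gain = 2,
                                  duration = 40, dt = 1, seed = seed,
                                  sigma = 0.5, neuron_radius = 15,
                                  init_range = c(10, 60))
  idx <- association_index_series(tr$tracks)
  add("association_index_mean", mean(idx$index), mean(idx$index) > 0)
  sp <- speed_by_radius_fold(tr$tracks, tr$neuron$radius)
  v <- sp$mean_speed_um_min[!is.na(sp$mean_speed_um_min)]
  add("speed_decreases_with_fold", utils::tail(v, 1) - v[1],
      all(diff(v) < 0))
  base <- simulate_lfp(fs = 1000, duration = 60, gamma_power = 0, seed = seed)
  bg <- attr(base, "background_band_power")
  test <- simulate_lfp(fs = 1000, duration = 60, gamma_power = 2 * bg,
                       seed = seed + 1)
  ratio <- band_power(lfp_psd(test, 1000), baseline = lfp_psd(base, 1000))
  add("gamma_ratio_recovery", as.numeric(ratio),
      abs(as.numeric(ratio) - 3) < 0.45)
  do.call(rbind, checks)
}
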