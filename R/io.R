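#' Write a simulated volume to disk
#'
#' One multi-page TIFF per intensity channel (float pages, z as pages) and
#' one per label channel (labels scaled to `[0, 1]` by the maximum id,
#' recorded in the sidecar), plus the ground truth as CSV and the
#' configuration and scaling metadata as YAML.
#'
#' @param sim result of [simulate_volume()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of files written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vol <- sim$volume
  files <- character()
  meta <- list(voxel_size_um_zyx = vol$voxel_size,
               axis_order = "zyx", label_scale = list())
  slices <- function(a) lapply(seq_len(dim(a)[1]), function(i) a[i, , ])
  for (nm in names(vol$channels)) {
    f <- file.path(dir, paste0("channel_", nm, ".tif"))
    a <- vol$channels[[nm]]
    r <- range(a)
    a <- (a - r[1]) / max(diff(r), .Machine$double.eps)
    tiff::writeTIFF(slices(a), f, bits.per.sample = 32L, reduce = FALSE)
    files <- c(files, f)
  }
  for (nm in names(vol$labels)) {
    f <- file.path(dir, paste0("labels_", nm, ".tif"))
    a <- vol$labels[[nm]]
    mx <- max(1L, max(a))
    tiff::writeTIFF(slices(a / mx), f, bits.per.sample = 32L, reduce = FALSE)
    meta$label_scale[[nm]] <- mx
    files <- c(files, f)
  }
  gt_pairs <- file.path(dir, "ground_truth_pairs.csv")
  gt_punc <- file.path(dir, "ground_truth_puncta.csv")
  write.csv(sim$ground_truth$pairs, gt_pairs, row.names = FALSE)
  write.csv(sim$ground_truth$puncta, gt_punc, row.names = FALSE)
  cfgf <- file.path(dir, "config.yaml")
  cfg <- sim$config
  cfg$volume_shape <- as.integer(vol$dims)
  yaml::write_yaml(c(unclass(cfg), list(metadata = meta)), cfgf)
  invisible(c(files, gt_pairs, gt_punc, cfgf))
}

#' Read a trajectory table
#'
#' Expects columns `id` (or `microglia_id`), `t_min`, `x_um`, `y_um` and
#' optionally `distance_um`.
#'
#' @param path CSV file.
#' @export
read_tracks_csv <- function(path) {
  df <- read.csv(path)
  if ("id" %in% names(df) && !"microglia_id" %in% names(df)) {
    names(df)[names(df) == "id"] <- "microglia_id"
  }
  need <- c("microglia_id", "t_min")
  if (!all(need %in% names(df))) {
    stopf("trajectory table needs columns %s", paste(need, collapse = ", "))
  }
  df
}

# run manifest: config hash, seeds, package version, file list, parameters
write_manifest <- function(dir, config_file, seed, params, outputs) {
  manifest <- list(
    package = "periglia",
    version = as.character(utils::packageVersion("periglia")),
    config_md5 = unname(tools::md5sum(config_file)),
    seed = seed,
    parameters = params,
    outputs = basename(outputs),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  f <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE)
  f
}
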