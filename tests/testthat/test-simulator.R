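test_that("config validation rejects impossible designs", {
  expect_error(tissue_config(p_assoc = 1.2), "p_assoc")
  expect_error(tissue_config(coverage_assoc = 0.05, coverage_nonassoc = 0.1),
               "exceed")
  expect_error(tissue_config(n_neurons = 1, n_microglia = 2), "exceed")
  expect_error(tissue_config(puncta_density = -1), "> 0")
  expect_error(tissue_config(max_axis_ratio = 2), "axis_ratio")
})

test_that("p_assoc = 0 plants no associated pairs and no relocations", {
  cfg <- tissue_config(n_neurons = 2, n_microglia = 2, p_assoc = 0,
                       coverage_nonassoc = 0, voxel_size = c(0.6, 0.6, 0.6),
                       render = FALSE, seed = 3)
  sim <- simulate_volume(cfg)
  expect_false(any(sim$ground_truth$pairs$associated))
  expect_identical(sum(sim$ground_truth$pairs$puncta_relocated), 0L)
})

test_that("same config and seed reproduce bit-identical output", {
  cfg <- tissue_config(n_neurons = 1, n_microglia = 1,
                       voxel_size = c(0.6, 0.6, 0.6), seed = 9)
  a <- simulate_volume(cfg)
  b <- simulate_volume(cfg)
  expect_identical(a$volume$labels, b$volume$labels)
  expect_identical(a$volume$channels, b$volume$channels)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("relocate mode conserves the pre-displacement draw per pair", {
  for (s in 1:5) {
    cfg <- tissue_config(n_neurons = 2, n_microglia = 2, p_assoc = 0.7,
                         voxel_size = c(0.6, 0.6, 0.6), render = FALSE,
                         seed = s)
    gt <- simulate_volume(cfg)$ground_truth$pairs
    expect_identical(gt$puncta_on_neuron + gt$puncta_relocated,
                     gt$puncta_total_draw)
  }
  # suppress mode deletes instead
  cfg <- tissue_config(n_neurons = 1, n_microglia = 1, p_assoc = 1,
                       displacement_mode = "suppress",
                       voxel_size = c(0.6, 0.6, 0.6), render = FALSE,
                       seed = 2)
  gt <- simulate_volume(cfg)$ground_truth$pairs
  expect_identical(gt$puncta_relocated, 0L)
  expect_lt(gt$puncta_on_neuron, gt$puncta_total_draw)
})

test_that("puncta lie within 0.25 um of their host surface or inside it", {
  cfg <- tissue_config(n_neurons = 2, n_microglia = 2, p_assoc = 1,
                       engulf_rate = 4, voxel_size = c(0.6, 0.6, 0.6),
                       render = FALSE, seed = 5)
  sim <- simulate_volume(cfg)
  gt <- sim$ground_truth$puncta
  geo <- sim$geometry
  rad_resid <- function(p, e) {
    u <- (p - e$center) %*% e$rot / e$axes
    (sqrt(sum(u^2)) - 1) * mean(e$axes)
  }
  for (k in seq_len(nrow(gt))) {
    p <- c(gt$z[k], gt$y[k], gt$x[k])
    if (gt$host[k] == "neuron_surface") {
      e <- geo$neurons[[gt$neuron_id[k]]]
      expect_lt(abs(rad_resid(p, e)), 0.25)
    } else if (gt$host[k] == "microglia_surface") {
      e <- geo$microglia[[gt$microglia_id[k]]]
      expect_lt(abs(rad_resid(p, e)), 0.25)
    } else {
      e <- geo$microglia[[gt$microglia_id[k]]]
      expect_lt(rad_resid(p, e), -0.25)  # strictly interior
    }
  }
})

test_that("realized voxel-oracle coverage tracks the planted coverage", {
  errs <- c()
  for (s in 1:10) {
    cfg <- tissue_config(n_neurons = 1, n_microglia = 1, p_assoc = 1,
                         render = FALSE, seed = 100 + s)
    sim <- simulate_volume(cfg)
    o <- coverage_voxel_oracle(sim$volume$labels$neuron == 1,
                               sim$volume$labels$microglia == 1,
                               sim$volume$voxel_size,
                               cfg$delta_contact)
    errs <- c(errs, o - sim$ground_truth$pairs$planted_coverage_3d)
  }
  expect_lt(max(abs(errs)), 0.03)
})

test_that("a half-engulfing microglia realizes coverage 0.5", {
  # finer grid than the confocal default so discretization error stays
  # well inside the band being tested
  cfg <- tissue_config(n_neurons = 1, n_microglia = 1, p_assoc = 1,
                       coverage_assoc = 0.5, coverage_jitter = 0,
                       microglia_radius_um = c(7, 0.05),
                       voxel_size = c(0.3, 0.15, 0.15),
                       render = FALSE, seed = 4)
  sim <- simulate_volume(cfg)
  o <- coverage_voxel_oracle(sim$volume$labels$neuron == 1,
                             sim$volume$labels$microglia == 1,
                             sim$volume$voxel_size, cfg$delta_contact)
  expect_gt(o, 0.47)
  expect_lt(o, 0.53)
})

test_that("infeasible packing fails with an explicit message", {
  cfg <- tissue_config(n_neurons = 1, n_microglia = 1, p_assoc = 1,
                       coverage_assoc = 0.45,
                       microglia_radius_um = c(2.5, 0.05),
                       render = FALSE, seed = 1)
  expect_error(simulate_volume(cfg), "coverage")
  cfg2 <- tissue_config(n_neurons = 1, n_microglia = 1,
                        volume_shape = c(10, 10, 10), render = FALSE,
                        seed = 1)
  expect_error(simulate_volume(cfg2), "too small")
})

test_that("rendered puncta appear as anisotropic spots at true centres", {
  cfg <- tissue_config(n_neurons = 1, n_microglia = 1, snr = 50, seed = 12)
  sim <- simulate_volume(cfg)
  gt <- sim$ground_truth$puncta
  vol <- sim$volume$channels$puncta
  vs <- sim$volume$voxel_size
  # intensity at each true centre voxel is near the peak amplitude
  ci <- cbind(pmin(pmax(round(gt$z / vs[1] + 0.5), 1), dim(vol)[1]),
              pmin(pmax(round(gt$y / vs[2] + 0.5), 1), dim(vol)[2]),
              pmin(pmax(round(gt$x / vs[3] + 0.5), 1), dim(vol)[3]))
  vals <- vol[ci]
  expect_gt(median(vals), 0.5)
})
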