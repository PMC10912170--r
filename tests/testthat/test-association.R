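test_that("disjoint somata have zero contact", {
  fx <- two_sphere_volume(r_n = 4, r_m = 3, dist = 17,
                          voxel_size = c(0.5, 0.4, 0.4))
  ns <- build_surfaces(fx$vol, "neuron")[[1]]
  ms <- build_surfaces(fx$vol, "microglia")[[1]]
  p <- contact_patch(ns, ms, 0.2)
  expect_identical(p$contact_area, 0)
  expect_identical(p$coverage_3d, 0)
  expect_equal(coverage_voxel_oracle(fx$vol$labels$neuron == 1,
                                     fx$vol$labels$microglia == 1,
                                     fx$vol$voxel_size, 0.2), 0)
})

test_that("a sphere half-embedded in a slab has coverage ~ 0.5", {
  vs <- c(0.4, 0.3, 0.3)
  dims <- c(50, 60, 60)
  ctr <- dims * vs / 2
  lab_n <- array(0L, dims)
  lab_n[sphere_mask(dims, vs, ctr, 5)] <- 1L
  idx <- arrayInd(seq_len(prod(dims)), dims)
  zc <- (idx[, 1] - 0.5) * vs[1]
  lab_m <- array(as.integer(zc <= ctr[1]), dims)   # half-space slab
  vol <- labeled_volume(list(neuron = lab_n, microglia = lab_m), vs)
  ns <- build_surfaces(vol, "neuron")[[1]]
  ms <- build_surfaces(vol, "microglia")[[1]]
  p <- contact_patch(ns, ms, 0.2)
  expect_lt(abs(p$coverage_3d - 0.5), 0.04)
})

test_that("contact is monotone in delta_contact", {
  fx <- two_sphere_volume(r_n = 5, r_m = 4.5, dist = 8.6,
                          voxel_size = c(0.5, 0.4, 0.4))
  ns <- build_surfaces(fx$vol, "neuron")[[1]]
  ms <- build_surfaces(fx$vol, "microglia")[[1]]
  deltas <- c(0.1, 0.2, 0.5, 1, 2)
  areas <- vapply(deltas, function(d) contact_patch(ns, ms, d)$contact_area,
                  numeric(1))
  expect_true(all(diff(areas) >= 0))
  expect_error(contact_patch(ns, ms, 0), "delta_contact")
})

test_that("mesh coverage agrees with the planted value on simulated pairs", {
  cfg <- tissue_config(n_neurons = 1, n_microglia = 1, p_assoc = 1,
                       coverage_assoc = 0.30,
                       microglia_radius_um = c(5.2, 0.1),
                       render = FALSE, seed = 21)
  sim <- simulate_volume(cfg)
  ns <- build_surfaces(sim$volume, "neuron")[[1]]
  ms <- build_surfaces(sim$volume, "microglia")[[1]]
  p <- contact_patch(ns, ms, 0.2)
  expect_lt(abs(p$coverage_3d - sim$ground_truth$pairs$planted_coverage_3d),
            0.03)
})

test_that("2D coverage handles the trivial and half-moon fixtures", {
  ny <- nx <- 200
  vs <- c(0.2, 0.2)
  yy <- outer((seq_len(ny) - 0.5) * 0.2, rep(1, nx))
  xx <- outer(rep(1, ny), (seq_len(nx) - 0.5) * 0.2)
  rr <- (yy - 20)^2 + (xx - 20)^2
  neuron <- rr <= 8^2
  expect_identical(coverage_2d(neuron, neuron & FALSE, vs), 0)
  annulus <- rr > 8^2 & rr <= 10^2
  expect_equal(coverage_2d(neuron, annulus, vs, 0.3), 1, tolerance = 0.01)
  halfmoon <- annulus & xx >= 20
  got <- coverage_2d(neuron, halfmoon, vs, 0.3)
  oracle <- coverage_2d_pixel_oracle(neuron, halfmoon, vs, 0.3)
  expect_equal(got, 0.5, tolerance = 0.03)
  expect_equal(got, oracle, tolerance = 0.03)
  expect_error(coverage_2d(neuron & FALSE, annulus, vs), "absent")
})

test_that("calibration fit recovers the printed regression exactly", {
  x <- c(5, 10, 20, 25, 30, 40)
  y <- 0.545 * x - 0.355
  m <- fit_calibration(x, y)
  expect_equal(m$slope, 0.545, tolerance = 1e-12)
  expect_equal(m$intercept, -0.355, tolerance = 1e-12)
  expect_equal(m$r2, 1, tolerance = 1e-12)
  expect_identical(m$n_cells, 6L)
})

test_that("OLS matches the closed-form normal equations", {
  set.seed(3)
  x <- runif(10, 0, 40)
  y <- 0.5 * x + rnorm(10)
  m <- fit_calibration(x, y)
  xb <- cbind(1, x)
  beta <- solve(t(xb) %*% xb, t(xb) %*% y)
  expect_equal(m$intercept, beta[1], tolerance = 1e-10)
  expect_equal(m$slope, beta[2], tolerance = 1e-10)
  # constant response -> slope 0; constant predictor -> error
  expect_equal(fit_calibration(x, rep(2, 10))$slope, 0, tolerance = 1e-12)
  expect_error(fit_calibration(rep(1, 10), y), "degenerate")
  expect_error(fit_calibration(1:2, 1:2), ">= 3")
})

test_that("threshold mapping reproduces the published 3D criterion", {
  m <- list(slope = 0.545, intercept = -0.355)
  expect_identical(map_threshold(m, 25), 13.27)
  expect_identical(map_threshold(list(slope = 1, intercept = 0), 25), 25)
  expect_identical(map_threshold(list(slope = 2, intercept = 0), 10), 20)
})

test_that("association classification applies thresholds inclusively", {
  rec <- data.frame(coverage_3d = c(0.1327, 0.1326, 0.5, 0),
                    coverage_2d = c(0.25, 0.26, 0.5, 0.2))
  out <- classify_association(rec)
  expect_identical(out$extensive_3d, c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(out$extensive_2d, c(FALSE, TRUE, TRUE, FALSE))
  # summary: 3 of 10 extensive -> 30%
  rec2 <- data.frame(coverage_3d = c(rep(0.2, 3), rep(0.05, 7)),
                     region = "M1", animal = 1)
  s <- attr(classify_association(rec2), "summary")
  expect_equal(s$pct_extensive, 30)
  expect_error(classify_association(rec2[0, ]), "no association")
})

test_that("2D and 3D classification are concordant after calibration", {
  # calibration round trip on simulated pairs spanning the thresholds
  cov2 <- cov3 <- c()
  for (s in 1:14) {
    target <- 0.06 + 0.28 * (s - 1) / 13
    cfg <- tissue_config(n_neurons = 1, n_microglia = 1, p_assoc = 1,
                         coverage_assoc = max(target, 0.08),
                         coverage_nonassoc = 0.01, coverage_jitter = 0,
                         microglia_radius_um = c(5.4, 0.05),
                         axis_tilt_max_deg = 20,
                         voxel_size = c(0.5, 0.3, 0.3),
                         render = FALSE, seed = 400 + s)
    sim <- simulate_volume(cfg)
    ns <- build_surfaces(sim$volume, "neuron")[[1]]
    ms <- build_surfaces(sim$volume, "microglia")[[1]]
    cov3 <- c(cov3, contact_patch(ns, ms, 0.2)$coverage_3d)
    zi <- max(1, round(ns$centroid[1] / 0.5))
    cov2 <- c(cov2, coverage_2d(sim$volume$labels$neuron[zi, , ] == 1,
                                sim$volume$labels$microglia[zi, , ] == 1,
                                c(0.3, 0.3), 0.2))
  }
  cal <- fit_calibration(100 * cov2, 100 * cov3)
  expect_gt(cal$r2, 0.7)
  thr3 <- map_threshold(cal, 25)
  cls2 <- 100 * cov2 > 25
  cls3 <- 100 * cov3 >= thr3
  expect_gte(mean(cls2 == cls3), 0.9)
})
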