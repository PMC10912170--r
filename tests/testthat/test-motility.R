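test_that("movement classification follows the epsilon rule", {
  tr <- data.frame(t_min = 0:5, distance_um = rep(10, 6))
  expect_true(all(classify_movement(tr)$class == 0L))
  tr2 <- data.frame(t_min = 0:5, distance_um = 20 - 2 * (0:5))
  expect_true(all(classify_movement(tr2, epsilon = 1)$class == 1L))
  tr3 <- data.frame(t_min = 0:4,
                    distance_um = 10 + c(0, -0.1, 0, -0.1, 0))
  expect_identical(classify_movement(tr3, epsilon = 0)$class,
                   c(1L, -1L, 1L, -1L))
  expect_error(classify_movement(tr[1, , drop = FALSE]), "frames")
  bad <- data.frame(t_min = c(0, 1, 1), distance_um = 1:3)
  expect_error(classify_movement(bad), "increasing")
})

test_that("association index sums classes with bounds", {
  mk <- function(id, dists) data.frame(microglia_id = id,
                                       t_min = seq_along(dists) - 1,
                                       distance_um = dists)
  # 5 towards, 2 away, 3 immobile at t = 0 -> index 3
  tracks <- rbind(
    do.call(rbind, lapply(1:5, function(i) mk(i, c(10, 8)))),
    do.call(rbind, lapply(6:7, function(i) mk(i, c(10, 12)))),
    do.call(rbind, lapply(8:10, function(i) mk(i, c(10, 10)))))
  expect_identical(association_index(tracks, 0), 3L)
  # all immobile -> 0
  im <- do.call(rbind, lapply(1:4, function(i) mk(i, c(5, 5, 5))))
  expect_identical(association_index(im, 1), 0L)
  # missing frame -> excluded with warning
  short <- rbind(mk(1, c(10, 8, 6)), mk(2, c(10, 8)))
  expect_warning(ix <- association_index(short, 1), "excluded")
  expect_identical(ix, 1L)
})

test_that("drift-free walks have near-zero net approach; drift pulls in", {
  tr0 <- simulate_coculture_tracks(250, drift = 0, speed_gain = 0,
                                   duration = 20, dt = 1, seed = 5,
                                   sigma = 0.5, neuron_radius = 15)
  net <- tapply(tr0$tracks$distance_um, tr0$tracks$microglia_id,
                function(v) v[length(v)] - v[1])
  # |mean net drift| small (the residual is the outward diffusion bias of
  # a 2D walk around a convex obstacle)
  expect_lt(abs(mean(net)), 0.6)
  trp <- simulate_coculture_tracks(250, drift = 1.2, speed_gain = 0,
                                   duration = 20, dt = 1, seed = 5,
                                   sigma = 0.5, neuron_radius = 15)
  netp <- tapply(trp$tracks$distance_um, trp$tracks$microglia_id,
                 function(v) v[length(v)] - v[1])
  expect_lt(mean(netp), -5)
  # negating the drift mirrors the expected index sign
  trm <- simulate_coculture_tracks(250, drift = -1.2, speed_gain = 0,
                                   duration = 20, dt = 1, seed = 5,
                                   sigma = 0.5, neuron_radius = 15)
  ip <- association_index_series(trp$tracks, epsilon = 0.5)
  im <- association_index_series(trm$tracks, epsilon = 0.5)
  expect_gt(mean(ip$index), 0)
  expect_lt(mean(im$index), 0)
  # dt = duration -> exactly 2 frames
  tr2 <- simulate_coculture_tracks(3, drift = 0, speed_gain = 0,
                                   duration = 5, dt = 5, seed = 1)
  expect_identical(nrow(tr2$tracks), 6L)
  expect_error(simulate_coculture_tracks(2, dt = 0), "dt")
})

test_that("speed bins are exact for a constructed track and NA when empty", {
  # single track approaching 4 um/min entirely inside fold [2, 3)
  tr <- data.frame(microglia_id = 1, t_min = 0:2,
                   distance_um = c(28, 24, 20))
  sp <- speed_by_radius_fold(tr, neuron_radius = 20,
                             fold_edges = c(1, 2, 3, 4))
  expect_equal(sp$mean_speed_um_min[2], 4)
  expect_true(is.na(sp$mean_speed_um_min[1]))
  expect_true(is.na(sp$mean_speed_um_min[3]))
  # no approach intervals -> all bins missing
  tr2 <- data.frame(microglia_id = 1, t_min = 0:2,
                    distance_um = c(20, 20, 20))
  expect_true(all(is.na(speed_by_radius_fold(tr2, 20)$mean_speed_um_min)))
  expect_error(speed_by_radius_fold(tr, 20, fold_edges = 1), "increasing")
})

test_that("approach speed increases toward the soma with speed_gain > 0", {
  tr <- simulate_coculture_tracks(200, drift = 1.2, speed_gain = 2,
                                  duration = 40, dt = 1, seed = 6,
                                  sigma = 0.5, neuron_radius = 15,
                                  init_range = c(10, 60))
  sp <- speed_by_radius_fold(tr$tracks, 15)
  v <- sp$mean_speed_um_min
  expect_true(all(!is.na(v)))
  expect_true(all(diff(v) < 0))   # inner bins faster
})
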