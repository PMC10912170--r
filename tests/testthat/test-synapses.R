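test_that("spot detection finds isolated rendered puncta precisely", {
  vs <- c(0.5, 0.2, 0.2)
  dims <- c(24, 60, 60)
  truth <- rbind(c(6, 4, 4), c(6, 4, 6), c(4.5, 8, 9))
  gt <- data.frame(z = truth[, 1], y = truth[, 2], x = truth[, 3])
  vol <- periglia:::render_puncta(gt, dims, vs)
  sp <- detect_spots(vol, vs)
  expect_identical(nrow(sp), 3L)
  for (k in 1:3) {
    d <- sqrt((sp$z - truth[k, 1])^2 + (sp$y - truth[k, 2])^2 +
                (sp$x - truth[k, 3])^2)
    expect_lt(min(d), 0.15)
  }
  # zero-intensity volume -> no spots
  expect_identical(nrow(detect_spots(array(0, dims), vs)), 0L)
  # two puncta 2 um apart resolve into 2 spots (checked above: spots 1-2)
})

test_that("spot classes follow the signed-distance precedence rules", {
  fx <- two_sphere_volume(r_n = 5, r_m = 4, dist = 8,
                          voxel_size = c(0.4, 0.25, 0.25))
  ns <- build_surfaces(fx$vol, "neuron")[[1]]
  ms <- build_surfaces(fx$vol, "microglia")[[1]]
  cn <- fx$center_neuron; cm <- fx$center_microglia
  spots <- data.frame(
    z = c(cn[1], cn[1], cn[1], cm[1], cm[1]),
    y = c(cn[2], cn[2], cn[2], cm[2], cm[2]),
    x = c(cn[3] - 5.3,   # 0.3 outside the neuron
          cn[3] - 5.7,   # 0.7 outside both -> other
          cn[3] + 2,     # deep inside the neuron -> other
          cm[3] + 4.3,   # 0.3 outside the microglia
          cm[3]))        # centre of the microglia -> engulfed
  cls <- classify_spots(spots, ns, ms, band = 0.5)
  expect_identical(cls$class,
                   c("on_neuron", "other", "other", "on_microglia",
                     "engulfed"))
  # engulfed call matches the voxel inside-test oracle
  vs <- fx$vol$voxel_size
  ci <- round(c(cm[1] / vs[1], cm[2] / vs[2], cm[3] / vs[3]) + 0.5)
  expect_identical(fx$vol$labels$microglia[ci[1], ci[2], ci[3]], 1L)
  expect_error(classify_spots(spots, ns, ms, band = 0), "band")
})

test_that("widening the band never decreases on-surface counts", {
  cfg <- tissue_config(n_neurons = 1, n_microglia = 1, p_assoc = 1,
                       render = FALSE, voxel_size = c(0.5, 0.3, 0.3),
                       seed = 8)
  sim <- simulate_volume(cfg)
  ns <- build_surfaces(sim$volume, "neuron")[[1]]
  ms <- build_surfaces(sim$volume, "microglia")[[1]]
  gt <- sim$ground_truth$puncta
  counts <- sapply(c(0.25, 0.5, 1, 2), function(b) {
    cls <- classify_spots(gt, ns, ms, band = b)
    c(sum(cls$class %in% c("on_neuron", "on_microglia")),
      sum(cls$class == "on_microglia"))
  })
  # on_microglia and the on-surface union are monotone; on_neuron alone is
  # not, because precedence moves near-contact puncta to on_microglia as
  # the band widens
  expect_true(all(diff(counts[1, ]) >= 0))
  expect_true(all(diff(counts[2, ]) >= 0))
})

test_that("per-pair tallies conserve the planted draw at fine resolution", {
  cfg <- tissue_config(n_neurons = 1, n_microglia = 1, p_assoc = 1,
                       render = FALSE, voxel_size = c(0.5, 0.25, 0.25),
                       seed = 31)
  sim <- simulate_volume(cfg)
  res <- analyze_volume(sim$volume, spots = sim$ground_truth$puncta,
                        fast = FALSE)
  gt <- sim$ground_truth$pairs
  # pair totals are conserved exactly; the on_neuron/on_microglia split may
  # shift by a few puncta at the contact rim, where the precedence rule
  # assigns near-contact puncta to the microglial surface
  expect_identical(res$n_pair_total, gt$puncta_total_draw)
  expect_lte(abs(res$n_on_neuron - gt$puncta_on_neuron), 5)
  expect_gte(res$n_on_microglia, gt$puncta_relocated)
  expect_identical(res$n_engulfed, gt$puncta_engulfed)
})

test_that("tally arithmetic and the outside-contact density are exact", {
  patch <- list(contact_area = 50, face_areas = c(rep(1, 250), rep(0.5, 100)),
                face_contact = c(rep(TRUE, 50), rep(FALSE, 300)))
  # neuron area 300 um^2, contact 50 um^2, 10 on-neuron spots outside
  spots <- data.frame(class = rep("on_neuron", 10),
                      nearest_neuron_face = 51:60)
  t1 <- tally_pair(spots, patch)
  expect_identical(t1$n_on_neuron, 10L)
  expect_identical(t1$n_pair_total, 10L)
  expect_equal(t1$density_outside_contact, 10 / 250)
  # no spots -> zeros
  t0 <- tally_pair(spots[0, ], patch)
  expect_identical(t0$n_on_neuron, 0L)
  expect_identical(t0$density_outside_contact, 0)
  # contact covering the whole soma -> density missing
  patch_full <- list(contact_area = 300,
                     face_areas = c(rep(1, 250), rep(0.5, 100)),
                     face_contact = rep(TRUE, 350))
  expect_true(is.na(tally_pair(spots, patch_full)$density_outside_contact))
})

test_that("external spot tables are accepted with unit checking", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = c(1, 2), y = c(3, 4), z = c(5, 6)), f,
            row.names = FALSE)
  sp <- read_spots_csv(f)
  expect_identical(sp$id, 1:2)
  f2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), f2, row.names = FALSE)
  expect_error(read_spots_csv(f2), "columns x, y, z")
})
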