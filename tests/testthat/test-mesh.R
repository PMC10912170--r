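test_that("voxelized sphere meshes to the analytic area within 5%", {
  vs <- c(0.5, 0.2, 0.2)
  r <- 5
  dims <- ceiling(2 * (r + 2) / vs)
  ctr <- dims * vs / 2
  mask <- sphere_mask(dims, vs, ctr, r)
  m <- periglia:::mesh_from_mask(mask, vs, smooth_sigma_vox = 1)
  expect_lt(abs(mesh_area(m$vertices, m$faces) / (4 * pi * r^2) - 1), 0.05)
  expect_lt(abs(mesh_volume(m$vertices, m$faces) / (4 / 3 * pi * r^3) - 1),
            0.05)
})

test_that("meshes are closed and genus-0 on sphere fixtures", {
  for (vs in list(c(0.5, 0.2, 0.2), c(0.5, 0.5, 0.5))) {
    dims <- ceiling(14 / vs)
    mask <- sphere_mask(dims, vs, dims * vs / 2, 5)
    m <- periglia:::mesh_from_mask(mask, vs, smooth_sigma_vox = 1)
    expect_identical(mesh_boundary_edges(m$faces), 0L)
    expect_identical(mesh_euler_characteristic(m$vertices, m$faces), 2L)
    expect_gt(mesh_volume(m$vertices, m$faces), 0)  # outward normals
  }
})

test_that("metric respects anisotropic voxel size on an ellipsoid", {
  # axis-aligned ellipsoid semi-axes (3, 5, 4) um on an anisotropic grid
  vs <- c(0.5, 0.2, 0.25)
  ax <- c(3, 5, 4)
  dims <- ceiling(2 * (ax + 2) / vs)
  mask <- ellipsoid_mask(dims, vs, dims * vs / 2, ax)
  m <- periglia:::mesh_from_mask(mask, vs, smooth_sigma_vox = 1)
  vol_true <- 4 / 3 * pi * prod(ax)
  expect_lt(abs(mesh_volume(m$vertices, m$faces) / vol_true - 1), 0.05)
  area_true <- periglia:::ellipsoid_area(ax)
  expect_lt(abs(mesh_area(m$vertices, m$faces) / area_true - 1), 0.05)
  # extent of the mesh matches the semi-axes per anisotropic axis
  rng <- apply(m$vertices, 2, function(z) diff(range(z)))
  expect_equal(rng, 2 * ax, tolerance = 0.1)
})

test_that("signed distance is negative inside, positive outside, exact", {
  vs <- c(0.5, 0.25, 0.25)
  dims <- ceiling(16 / vs)
  ctr <- dims * vs / 2
  r <- 5
  mask <- sphere_mask(dims, vs, ctr, r)
  m <- periglia:::mesh_from_mask(mask, vs, smooth_sigma_vox = 1)
  pts <- rbind(ctr,                       # centre: inside, ~ -r
               ctr + c(0, 0, r + 1.5),    # outside by 1.5
               ctr + c(0, r - 0.5, 0))    # inside by 0.5
  d <- signed_distance(pts, m$vertices, m$faces)
  expect_equal(d$distance, c(-r, 1.5, -0.5), tolerance = 0.15)
  # fast backend agrees with the winding-number backend
  dfast <- periglia:::cpp_signed_distance_fast(pts, m$vertices, m$faces)
  expect_equal(dfast$distance, d$distance, tolerance = 1e-9)
})

test_that("contact mask equals thresholded exact signed distance", {
  fx <- two_sphere_volume(r_n = 4, r_m = 3.5, dist = 6.5,
                          voxel_size = c(0.5, 0.4, 0.4))
  ns <- build_surfaces(fx$vol, "neuron")[[1]]
  ms <- build_surfaces(fx$vol, "microglia")[[1]]
  fc <- mesh_face_centroids(ns$vertices, ns$faces)
  for (delta in c(0.2, 0.5, 1.0)) {
    exact <- signed_distance(fc, ms$vertices, ms$faces)$distance <= delta
    fast <- periglia:::cpp_contact_mask(fc, ms$vertices, ms$faces, delta)
    expect_identical(as.logical(fast), as.logical(exact))
  }
})

test_that("distance transform matches brute force on random masks", {
  set.seed(7)
  vs <- c(0.5, 0.3, 0.3)
  for (rep in 1:3) {
    dims <- c(8, 10, 9)
    mask <- array(runif(prod(dims)) < 0.08, dims)
    if (!any(mask)) mask[3, 4, 5] <- TRUE
    d <- periglia:::distance_to_mask(mask, vs)
    idx <- arrayInd(seq_len(prod(dims)), dims)
    p <- sweep(idx - 0.5, 2, vs, "*")
    feat <- p[as.vector(mask), , drop = FALSE]
    brute <- apply(p, 1, function(q) {
      sqrt(min(colSums((t(feat) - q)^2)))
    })
    expect_equal(as.vector(d), brute, tolerance = 1e-9)
  }
})

test_that("PLY export writes a parseable mesh", {
  vs <- c(0.5, 0.5, 0.5)
  mask <- sphere_mask(c(16, 16, 16), vs, c(4, 4, 4), 3)
  m <- periglia:::mesh_from_mask(mask, vs)
  f <- tempfile(fileext = ".ply")
  write_ply(m$vertices, m$faces, f)
  lines <- readLines(f)
  expect_identical(lines[1], "ply")
  nv <- as.integer(sub("element vertex ", "", grep("element vertex", lines,
                                                   value = TRUE)))
  expect_identical(nv, nrow(m$vertices))
})
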