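# geometric fixtures shared across tests; everything built in code

# voxelized ellipsoid mask: semi-axes `ax` (um, z/y/x), centre in um
ellipsoid_mask <- function(dims, voxel_size, center, ax) {
  idx <- arrayInd(seq_len(prod(dims)), dims)
  p <- sweep(idx - 0.5, 2, voxel_size, "*")
  u <- sweep(p, 2, center)
  u <- sweep(u, 2, ax, "/")
  array(rowSums(u^2) <= 1, dims)
}

sphere_mask <- function(dims, voxel_size, center, r) {
  ellipsoid_mask(dims, voxel_size, center, rep(r, 3))
}

# two-channel labelled volume with one neuron sphere and one microglia
# sphere at a prescribed centre distance
two_sphere_volume <- function(r_n = 5, r_m = 4.5, dist = 6,
                              voxel_size = c(0.5, 0.25, 0.25),
                              pad_um = 2) {
  ext <- c(2 * (max(r_n, r_m) + pad_um),
           2 * (r_n + pad_um) + 0,
           r_n + dist + r_m + 2 * pad_um)
  ext[2] <- max(ext[2], 2 * (max(r_n, r_m) + pad_um))
  dims <- ceiling(ext / voxel_size)
  c_n <- c(ext[1] / 2, ext[2] / 2, pad_um + r_n)
  c_m <- c_n + c(0, 0, dist)
  lab_n <- array(0L, dims); lab_n[sphere_mask(dims, voxel_size, c_n, r_n)] <- 1L
  lab_m <- array(0L, dims); lab_m[sphere_mask(dims, voxel_size, c_m, r_m)] <- 1L
  list(vol = labeled_volume(list(neuron = lab_n, microglia = lab_m),
                            voxel_size),
       center_neuron = c_n, center_microglia = c_m)
}

# tiny shared displacement cohort (computed once per test run)
.test_cache <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.test_cache$cohort)) {
    .test_cache$cohort <- simulate_pair_cohort(
      n_animals = 2, pairs_per_animal = 12, seed = 42,
      voxel_size = c(0.6, 0.6, 0.6), p_assoc = 0.5,
      displace_frac = 0.4, coverage_nonassoc = 0.02)
  }
  .test_cache$cohort
}
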