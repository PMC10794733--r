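# Small phantom builders shared by the tests.

# empty volume on a d-grid
vg0 <- function(d = c(8, 8, 8), voxel_size = c(1, 1, 1)) {
  volume_grid(array(0, d), voxel_size = voxel_size)
}

# volume with ones at the given voxel index rows (n x 3 matrix)
vg_at <- function(idx, d = c(8, 8, 8), voxel_size = c(1, 1, 1),
                  value = 1) {
  a <- array(0, d)
  idx <- matrix(idx, ncol = 3)
  a[idx] <- value
  volume_grid(a, voxel_size = voxel_size)
}

# straight vertical streamline at column (x, y) spanning z in [z0, z1]
column_fibre <- function(x, y, z0, z1) {
  cbind(c(x, x), c(y, y), c(z0, z1))
}

# z-slab waypoint mask restricted to x in xr (one hemisphere)
slab_waypoint <- function(z, xr, d = c(8, 8, 8)) {
  a <- array(0, d)
  a[xr[1]:xr[2], , z] <- 1
  volume_grid(a)
}

# small, fast generator configuration for pipeline-level tests
test_config <- function(seed = 42L, n_patients = 12L, ...) {
  synthetic_config(n_patients = n_patients, n_controls = 3L,
                   grid_shape = c(12L, 12L, 12L), voxel_size = c(2, 2, 2),
                   n_streamlines_per_control = 20L, seed = seed, ...)
}

# analysis table with known linear structure, no imaging involved; the
# six pseudo-measures share a latent damage factor (they are strongly
# mutually correlated, as the real measures are)
fake_analysis_data <- function(n, seed = 1L, measure_signal = 0) {
  set.seed(seed)
  d <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = runif(n, 28, 80), sex = rbinom(n, 1, 0.5),
    dominance = rbinom(n, 1, 0.5),
    fma_2w = round(runif(n, 4, 63)))
  latent <- rnorm(n)
  for (m in damage_measure_codes()) d[[m]] <- latent + rnorm(n, 0, 0.4)
  d$fma_3m <- round(pmin(66, pmax(4,
    10 + 0.6 * d$fma_2w + measure_signal * d$cst_lesion_load +
      rnorm(n, 0, 6))))
  d
}
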