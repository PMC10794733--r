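test_that("a single streamline through all three waypoints becomes a weight-1 trace", {
  wp <- list(slab_waypoint(2, c(1, 4)), slab_waypoint(5, c(1, 4)),
             slab_waypoint(8, c(1, 4)))
  s <- streamline_set(list(column_fibre(2, 3, 1, 8)))
  terr <- build_cst_territory(s, wp)
  w <- terr$weight_map$values
  expect_equal(sum(w > 0), 8)
  expect_true(all(w[2, 3, ] == 1))
})

test_that("midline-crossing streamlines are excluded from the territory", {
  wp <- list(slab_waypoint(2, c(1, 4)), slab_waypoint(5, c(1, 4)),
             slab_waypoint(8, c(1, 4)))
  crosser <- cbind(c(2, 7), c(3, 3), c(1, 8))  # drifts into x > 4.5
  keeper <- column_fibre(2, 3, 1, 8)
  terr <- build_cst_territory(streamline_set(list(keeper, crosser)), wp)
  expect_true(all(terr$weight_map$values[5:8, , ] == 0))
  expect_error(build_cst_territory(streamline_set(list(crosser)), wp),
               "empty territory")
})

test_that("pass-through counts are normalised to the maximum (hand-enumerated)", {
  # A: column at (2,3), z 1..8.  B: shares (2,3,1..3), then crosses
  # diagonally to (2,5,5) and continues up: voxel trace enumerated by hand.
  wp <- list(slab_waypoint(2, c(1, 4)), slab_waypoint(5, c(1, 4)),
             slab_waypoint(8, c(1, 4)))
  A <- column_fibre(2, 3, 1, 8)
  B <- rbind(c(2, 3, 1), c(2, 3, 3), c(2, 5, 5), c(2, 5, 8))
  terr <- build_cst_territory(streamline_set(list(A, B)), wp)
  w <- terr$weight_map$values
  shared <- rbind(c(2, 3, 1), c(2, 3, 2), c(2, 3, 3))
  a_only <- cbind(2, 3, 4:8)
  b_only <- rbind(c(2, 4, 4), c(2, 5, 5), c(2, 5, 6), c(2, 5, 7),
                  c(2, 5, 8))
  expect_equal(unname(w[shared]), rep(1, 3))
  expect_equal(unname(w[a_only]), rep(0.5, 5))
  expect_equal(unname(w[b_only]), rep(0.5, 5))
  expect_equal(sum(w > 0), 13)
})

test_that("exclusion-zone streamlines are dropped", {
  wp <- list(slab_waypoint(2, c(1, 4)), slab_waypoint(5, c(1, 4)),
             slab_waypoint(8, c(1, 4)))
  excl <- vg_at(c(2, 5, 6))
  A <- column_fibre(2, 3, 1, 8)
  B <- rbind(c(2, 3, 1), c(2, 3, 3), c(2, 5, 5), c(2, 5, 8))  # hits (2,5,6)
  terr <- build_cst_territory(streamline_set(list(A, B)), wp,
                              exclusion = excl)
  expect_true(all(terr$weight_map$values[2, 3, 1:8] == 1))
  expect_equal(sum(terr$weight_map$values > 0), 8)
})

test_that("control territory is the average of per-control normalised maps", {
  wp3 <- list(slab_waypoint(2, c(1, 4)), slab_waypoint(5, c(1, 4)),
              slab_waypoint(8, c(1, 4)))
  wp_r <- list(slab_waypoint(2, c(5, 8)), slab_waypoint(5, c(5, 8)),
               slab_waypoint(8, c(5, 8)))
  mk <- function(xl, xr) streamline_set(list(
    column_fibre(xl, 3, 1, 8), column_fibre(xr, 3, 1, 8)))
  ctl <- control_cst_territory(list(mk(2, 6), mk(3, 6)),
                               list(left = wp3, right = wp_r))
  w <- ctl$weight_map$values
  expect_equal(unname(w[2, 3, 4]), 0.5)  # present in one control only
  expect_equal(unname(w[3, 3, 4]), 0.5)
  expect_equal(unname(w[6, 3, 4]), 1)    # present in both
  expect_equal(ctl$kind, "control")
})

test_that("disconnectome matches hand-enumerated counts and warns when empty", {
  d <- c(8, 8, 8)
  c1 <- streamline_set(list(column_fibre(2, 3, 1, 4)), "c1")
  c2 <- streamline_set(list(cbind(c(2, 2), c(3, 6), c(4, 4))), "c2")
  lesion <- vg_at(c(2, 3, 4), d)
  disco <- build_disconnectome(lesion, list(c1, c2))
  w <- disco$values
  expect_equal(unname(w[2, 3, 4]), 1)            # both controls
  expect_equal(unname(w[2, 3, 1]), 0.5)          # c1 only
  expect_equal(unname(w[2, 5, 4]), 0.5)          # c2 only
  expect_true(all(w >= 0 & w <= 1))

  far <- vg_at(c(7, 7, 7), d)
  expect_warning(z <- build_disconnectome(far, list(c1, c2)),
                 "all zero")
  expect_true(all(z$values == 0))
})

test_that("FA asymmetry follows the contralesional-ipsilesional ratio", {
  d <- c(8, 4, 4)
  terr <- cst_territory(vg_at(rbind(c(2, 2, 2), c(6, 2, 2)), d))
  # uniform FA: asymmetry 0
  fa05 <- volume_grid(array(0.5, d))
  expect_equal(compute_fa_asymmetry(fa05, terr, "left"), 0)
  # contra 0.5 vs ipsi 0.3
  fa <- array(0.5, d); fa[2, 2, 2] <- 0.3
  expect_equal(compute_fa_asymmetry(volume_grid(fa), terr, "left"), 0.25)
  # antisymmetry under relabelling
  expect_equal(compute_fa_asymmetry(volume_grid(fa), terr, "right"), -0.25)
})

test_that("weighted FA means use territory weights (hand-summed oracle)", {
  d <- c(8, 4, 4)
  wmap <- array(0, d)
  wmap[2, 2, 2] <- 1; wmap[3, 2, 2] <- 0.5   # ipsilesional (left)
  wmap[6, 2, 2] <- 1; wmap[7, 2, 2] <- 0.5   # contralesional
  terr <- cst_territory(volume_grid(wmap))
  fa <- array(0.5, d); fa[2, 2, 2] <- 0.6; fa[3, 2, 2] <- 0.2
  ipsi <- (1 * 0.6 + 0.5 * 0.2) / 1.5
  expected <- (0.5 - ipsi) / (0.5 + ipsi)
  expect_equal(compute_fa_asymmetry(volume_grid(fa), terr, "left"),
               expected)
  # binarised mode ignores the weights
  ipsi_b <- (0.6 + 0.2) / 2
  expect_equal(compute_fa_asymmetry(volume_grid(fa), terr, "left",
                                    weighted = FALSE),
               (0.5 - ipsi_b) / (0.5 + ipsi_b))
  # empty hemisphere is an error
  half <- array(0, d); half[2, 2, 2] <- 1
  expect_error(compute_fa_asymmetry(volume_grid(fa),
                                    cst_territory(volume_grid(half)),
                                    "left"),
               "undefined asymmetry")
})

test_that("weighted overlap sums damage x ROI x voxel volume", {
  d <- c(8, 4, 4)
  lesion10 <- vg_at(cbind(rep(1:2, 5), rep(1:4, 3)[1:10], rep(1:2, 5)), d)
  brain <- volume_grid(array(1, d))
  expect_equal(compute_weighted_overlap(lesion10, brain),
               sum(lesion10$values))
  expect_equal(compute_weighted_overlap(vg0(d), brain), 0)
  # 3 lesion voxels against CST weights {1, 0.5, 0} at 2 mm voxels
  les <- vg_at(rbind(c(2, 2, 2), c(2, 2, 3), c(2, 2, 4)), d,
               voxel_size = c(2, 2, 2))
  cstw <- array(0, d); cstw[2, 2, 2] <- 1; cstw[2, 2, 3] <- 0.5
  roi <- volume_grid(cstw, voxel_size = c(2, 2, 2))
  expect_equal(compute_weighted_overlap(les, roi), (1 + 0.5 + 0) * 8)
  expect_error(compute_weighted_overlap(les, brain), "different grids")
})

test_that("all six measures respect the Table-2 damage-map/ROI pairing", {
  d <- c(8, 8, 8)
  wp_l <- list(slab_waypoint(2, c(1, 4), d), slab_waypoint(5, c(1, 4), d),
               slab_waypoint(8, c(1, 4), d))
  wp_r <- list(slab_waypoint(2, c(5, 8), d), slab_waypoint(5, c(5, 8), d),
               slab_waypoint(8, c(5, 8), d))
  wps <- list(left = wp_l, right = wp_r)
  pat <- streamline_set(list(column_fibre(2, 3, 1, 8),
                             column_fibre(6, 3, 1, 8)), "P")
  ctl <- list(streamline_set(list(column_fibre(2, 3, 1, 8),
                                  column_fibre(6, 3, 1, 8)), "C"))
  pat_t <- patient_cst_territory(pat, wps)
  ctl_t <- control_cst_territory(ctl, wps)

  # lesion of 2 voxels fully inside the (weight-1) control CST
  lesion <- vg_at(rbind(c(2, 3, 4), c(2, 3, 5)), d)
  fa <- volume_grid(array(0.5, d))
  img <- imaging_set(lesion, fa, "left")
  m <- compute_all_measures(img, pat_t, ctl_t, ctl)
  expect_s3_class(m, "damage_measure_set")
  expect_equal(m$patient_cst_fa_asym, 0)
  expect_equal(m$control_cst_fa_asym, 0)
  expect_equal(m$lesion_volume, 2)
  # lesion inside CST at weight 1: load = lesion volume x mean weight
  expect_equal(m$cst_lesion_load, 2)
  # disconnectome = the one intersecting fibre's trace at weight 1;
  # its overlap with the CST (8 voxels at weight 1) and brain
  expect_equal(m$cst_disconnectome_load, 8)
  expect_equal(m$disconnectome_volume, 8)

  # remote lesion: zero loads, intact asymmetries
  img2 <- imaging_set(vg_at(c(4, 7, 2), d), fa, "left")
  m2 <- suppressWarnings(
    compute_all_measures(img2, pat_t, ctl_t, ctl))
  expect_equal(m2$cst_lesion_load, 0)
  expect_equal(m2$cst_disconnectome_load, 0)
  expect_equal(m2$patient_cst_fa_asym, 0)
})

test_that("lesion superset monotonicity and voxel-size scale equivariance", {
  d <- c(8, 8, 8)
  wp_l <- list(slab_waypoint(2, c(1, 4), d), slab_waypoint(5, c(1, 4), d),
               slab_waypoint(8, c(1, 4), d))
  wp_r <- list(slab_waypoint(2, c(5, 8), d), slab_waypoint(5, c(5, 8), d),
               slab_waypoint(8, c(5, 8), d))
  wps <- list(left = wp_l, right = wp_r)
  set.seed(11)
  for (rep in 1:5) {
    fib_l <- lapply(1:3, function(i)
      column_fibre(sample(1:4, 1), sample(1:8, 1), 1, 8))
    fib_r <- lapply(1:3, function(i)
      column_fibre(sample(5:8, 1), sample(1:8, 1), 1, 8))
    ctl <- list(streamline_set(c(fib_l, fib_r), "C"))
    ctl_t <- control_cst_territory(ctl, wps)
    pat_t <- ctl_t  # geometry identical; kind irrelevant here

    vox_small <- sample(3, 1)
    idx_small <- cbind(sample(1:4, vox_small, TRUE),
                       sample(1:8, vox_small, TRUE),
                       sample(1:8, vox_small, TRUE))
    idx_big <- rbind(idx_small,
                     cbind(sample(1:4, 3, TRUE), sample(1:8, 3, TRUE),
                           sample(1:8, 3, TRUE)))
    fa <- volume_grid(array(0.5, d))
    small <- imaging_set(vg_at(idx_small, d), fa, "left")
    big <- imaging_set(vg_at(idx_big, d), fa, "left")
    ms <- suppressWarnings(compute_all_measures(small, pat_t, ctl_t, ctl))
    mb <- suppressWarnings(compute_all_measures(big, pat_t, ctl_t, ctl))
    for (f in c("cst_lesion_load", "cst_disconnectome_load",
                "lesion_volume", "disconnectome_volume"))
      expect_gte(mb[[f]], ms[[f]])

    # doubling the voxel size multiplies loads/volumes by 8 and leaves
    # the FA asymmetries unchanged
    scale_grid <- function(g) volume_grid(g$values, g$voxel_size * 2,
                                          g$split_axis)
    img2 <- imaging_set(scale_grid(small$lesion_mask),
                        scale_grid(small$fa_map), "left")
    pat2 <- cst_territory(scale_grid(pat_t$weight_map), "patient")
    ctl2 <- cst_territory(scale_grid(ctl_t$weight_map), "control")
    m2 <- suppressWarnings(compute_all_measures(img2, pat2, ctl2, ctl))
    for (f in c("cst_lesion_load", "cst_disconnectome_load",
                "lesion_volume", "disconnectome_volume"))
      expect_equal(m2[[f]], 8 * ms[[f]])
    expect_equal(m2$patient_cst_fa_asym, ms$patient_cst_fa_asym)
    expect_equal(m2$control_cst_fa_asym, ms$control_cst_fa_asym)
  }
})

test_that("partial correlations match a two-stage regression oracle", {
  set.seed(3)
  n <- 50
  Z <- data.frame(age = runif(n, 28, 80), sex = rbinom(n, 1, 0.5),
                  dominance = rbinom(n, 1, 0.5))
  latent <- rnorm(n)
  M <- data.frame(
    m1 = latent + 0.02 * Z$age + rnorm(n, 0, 0.3),
    m2 = latent - 0.5 * Z$sex + rnorm(n, 0, 0.3),
    m3 = -latent + 0.01 * Z$age + rnorm(n, 0, 0.3))
  pc <- partial_correlation_matrix(M, Z)

  # oracle: residualise each column with lm(), then plain Pearson
  oracle <- function(a, b) {
    ra <- resid(lm(a ~ age + sex + dominance, data = cbind(Z, a = a)))
    rb <- resid(lm(b ~ age + sex + dominance, data = cbind(Z, b = b)))
    cor(ra, rb)
  }
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(pc$estimate[i, j], oracle(M[[i]], M[[j]]),
                 tolerance = 1e-10)
  expect_equal(pc$estimate, t(pc$estimate))
  expect_equal(unname(diag(pc$estimate)), rep(1, 3))

  # constant covariates reduce partial correlation to plain correlation
  Zc <- data.frame(age = rep(50, n), sex = rep(1, n),
                   dominance = rep(0, n))
  pc_c <- partial_correlation_matrix(M, Zc)
  expect_equal(pc_c$estimate[1, 2], cor(M$m1, M$m2), tolerance = 1e-10)

  # duplicated measure: off-diagonal exactly 1
  pc_d <- partial_correlation_matrix(data.frame(a = M$m1, b = M$m1), Z)
  expect_equal(pc_d$estimate[1, 2], 1)
})

test_that("damage measures are mutually positively correlated on shared-geometry cohorts", {
  cfg <- test_config(seed = 5, n_patients = 25)
  co <- generate_cohort(cfg)
  ctl <- generate_control_streamlines(cfg)
  m <- suppressWarnings(cohort_damage_measures(co, ctl))
  cc <- cor(as.matrix(m[, -1]))
  expect_true(all(cc[upper.tri(cc)] > 0))
})
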