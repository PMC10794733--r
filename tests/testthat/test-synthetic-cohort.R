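test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(prop_severe = 1.2), "proportions")
  expect_error(synthetic_config(prop_nonfitted = -0.1), "proportions")
  expect_error(synthetic_config(grid_shape = c(6, 12, 12)), ">= 8")
  expect_error(synthetic_config(recovery_noise_sd = -1),
               "recovery_noise_sd")
})

test_that("generation is bitwise reproducible for a given seed", {
  cfg <- test_config(seed = 21)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$imaging[[1]]$lesion_mask$values,
                   b$imaging[[1]]$lesion_mask$values)
  expect_false(identical(generate_cohort(test_config(seed = 22))$records,
                         a$records))
})

test_that("noise-free fitted subjects follow the 0.7 rule to rounding", {
  cfg <- test_config(seed = 6, n_patients = 20, recovery_noise_sd = 0,
                     prop_nonfitted = 0)
  co <- generate_cohort(cfg)
  res <- prr_residual(co$records$fma_2w, co$records$fma_3m)
  expect_true(all(abs(res) <= 0.5))
  pred <- co$records$fma_2w + 0.7 * (66 - co$records$fma_2w)
  expect_equal(co$records$fma_3m, as.integer(round(pred)))
})

test_that("scores stay in the observed ranges and severe count is calibrated", {
  cfg <- synthetic_config(n_patients = 60, n_controls = 3,
                          grid_shape = c(12, 12, 12),
                          n_streamlines_per_control = 20,
                          prop_severe = 0.55, seed = 1)
  co <- generate_cohort(cfg)
  expect_true(all(co$records$fma_2w >= 4 & co$records$fma_2w <= 63))
  expect_true(all(co$records$fma_3m >= 4 & co$records$fma_3m <= 66))
  n_sev <- sum(co$records$fma_2w <= 20)
  # binomial 95% band around 33 of 60
  band <- qbinom(c(0.025, 0.975), 60, 0.55)
  expect_gte(n_sev, band[1])
  expect_lte(n_sev, band[2])
})

test_that("CST overlap is negatively coupled to baseline score", {
  cfg <- synthetic_config(n_patients = 200, n_controls = 3,
                          grid_shape = c(12, 12, 12),
                          n_streamlines_per_control = 20, seed = 8)
  co <- generate_cohort(cfg)
  expect_lt(cor(co$cst_overlap, co$records$fma_2w), 0)
})

test_that("non-fitted fraction lands in its binomial band", {
  cfg <- synthetic_config(n_patients = 200, n_controls = 3,
                          grid_shape = c(12, 12, 12),
                          n_streamlines_per_control = 20,
                          prop_nonfitted = 0.3, recovery_noise_sd = 0,
                          seed = 13)
  co <- generate_cohort(cfg)
  st <- assign_strata(co$records)
  n_nf <- sum(st$proportional_recovery == "non-fitted")
  band <- qbinom(c(0.025, 0.975), 200, 0.3)
  expect_gte(n_nf, band[1])
  expect_lte(n_nf, band[2])
})

test_that("control streamline sets honour the count and waypoint contracts", {
  cfg <- test_config(seed = 30, prop_background = 0)
  ctls <- generate_control_streamlines(cfg)
  expect_length(ctls, cfg$n_controls)
  expect_true(all(vapply(ctls, length, integer(1)) ==
                    cfg$n_streamlines_per_control))

  # with no background fibres, every streamline passes all three
  # waypoints of one hemisphere
  geom <- phantom_geometry(cfg$grid_shape, cfg$voxel_size)
  grid <- geom$waypoints$left[[1]]
  passes_all <- function(p, side) {
    v <- streamline_voxels(p, grid)
    all(vapply(geom$waypoints[[side]],
               function(w) any(v %in% which(w$values != 0)), logical(1)))
  }
  for (p in ctls[[1]]$streamlines)
    expect_true(passes_all(p, "left") || passes_all(p, "right"))

  # with background fibres, at least one crosses the midline
  ctls_bg <- generate_control_streamlines(test_config(seed = 30))
  idx <- index_streamlines(ctls_bg[[1]], grid)
  expect_true(any(idx$crosses_midline))
})

test_that("waypoint filtering retains exactly the bundle fibres", {
  # bundle fibres are generated first; background fibres follow
  cfg <- test_config(seed = 31, prop_background = 0.3)
  geom <- phantom_geometry(cfg$grid_shape, cfg$voxel_size)
  grid <- geom$waypoints$left[[1]]
  ctl <- generate_control_streamlines(cfg)[[1]]
  n_bundle <- cfg$n_streamlines_per_control -
    round(cfg$n_streamlines_per_control * cfg$prop_background)
  idx <- index_streamlines(ctl, grid)
  keep <- vapply(seq_along(idx$voxels), function(i) {
    v <- idx$voxels[[i]]
    ok_side <- function(side) all(vapply(
      geom$waypoints[[side]],
      function(w) any(v %in% which(w$values != 0)), logical(1)))
    !idx$crosses_midline[i] && (ok_side("left") || ok_side("right"))
  }, logical(1))
  expect_true(all(keep[seq_len(n_bundle)]))
  expect_false(any(keep[-seq_len(n_bundle)]))
})

test_that("lesion phantoms respect the cortical flag and hemisphere bounds", {
  cfg <- test_config(seed = 40, n_patients = 16)
  co <- generate_cohort(cfg)
  geom <- phantom_geometry(cfg$grid_shape, cfg$voxel_size)
  for (i in seq_len(16)) {
    img <- co$imaging[[i]]
    les <- img$lesion_mask$values != 0
    expect_gt(sum(les), 0)
    contra <- hemisphere_mask(img$lesion_mask,
                              opposite_side(img$ipsilesional_side))
    expect_false(any(les & contra))
    in_shell <- any(les & geom$cortical_shell)
    expect_equal(in_shell, co$records$cortical_flag[i] == 1)
    expect_true(all(img$fa_map$values >= 0 & img$fa_map$values <= 1))
  }
})

test_that("degenerate lesion requests are configuration errors", {
  cfg <- test_config(seed = 2)
  rec <- data.frame(subject_id = "P001", side = "left", cortical_flag = 0)
  expect_error(generate_lesion_and_fa(rec, cfg, radius = 0), "positive")
  expect_error(generate_lesion_and_fa(rec, cfg, radius = 50),
               "hemisphere")
})
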