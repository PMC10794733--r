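#' Configuration of the synthetic cohort generator
#'
#' Defaults reproduce the study conditions of the motivating cohort: 60
#' patients and 77 normative controls; baseline UE-FMA (2-week) scores in
#' 4--63 with 33/60 severe (score <= 20); 26/60 cortical lesions; MEPs
#' measured in 47/60 with 14/47 MEP-negative; 22/60 proportional-recovery
#' non-fitted; outcomes (3-month scores) following the 0.7 proportional
#' recovery rule plus noise for fitted subjects.
#'
#' @param n_patients,n_controls cohort sizes.
#' @param grid_shape integer length-3 phantom grid, all axes >= 8.
#' @param voxel_size mm per axis.
#' @param seed integer seed; all generator randomness derives from it.
#' @param prop_severe target fraction with baseline score <= 20.
#' @param prop_cortical fraction whose lesion extends into the cortical shell.
#' @param prop_mep_measured fraction with MEP status measured.
#' @param prop_nonfitted fraction violating the proportional recovery rule
#'   (model residual >= 20).
#' @param prop_mep_negative fraction of measured subjects without MEPs.
#' @param recovery_noise_sd UE-FMA points; sd of outcome noise around the
#'   proportional-recovery prediction.
#' @param damage_coupling unitless; strength of the negative coupling
#'   between CST lesion overlap and baseline score.
#' @param n_streamlines_per_control streamlines per control subject.
#' @param prop_background fraction of each streamline set that is background
#'   fibres (not constrained to the CST waypoints; some cross the midline).
#' @param membership_slope logistic slope (per sd of CST overlap) of the
#'   probability of being proportional-recovery non-fitted or MEP-negative;
#'   larger values make these labels more damage-determined.
#' @param deficit_noise_sd sd (on the normalised-overlap scale) of the
#'   noise in the non-fitted deficit; smaller values make recovery failure
#'   more predictable from structural damage.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 60L,
                             n_controls = 77L,
                             grid_shape = c(24L, 24L, 24L),
                             voxel_size = c(2, 2, 2),
                             seed = 1L,
                             prop_severe = 33 / 60,
                             prop_cortical = 26 / 60,
                             prop_mep_measured = 47 / 60,
                             prop_nonfitted = 22 / 60,
                             prop_mep_negative = 14 / 47,
                             recovery_noise_sd = 7,
                             damage_coupling = 0.8,
                             n_streamlines_per_control = 60L,
                             prop_background = 0.2,
                             membership_slope = 4,
                             deficit_noise_sd = 0.4) {
  fr <- c(prop_severe = prop_severe, prop_cortical = prop_cortical,
          prop_mep_measured = prop_mep_measured,
          prop_nonfitted = prop_nonfitted,
          prop_mep_negative = prop_mep_negative,
          prop_background = prop_background)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("configuration error: all proportions must lie in [0, 1]",
         call. = FALSE)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("configuration error: grid_shape axes must all be >= 8",
         call. = FALSE)
  if (!is.finite(recovery_noise_sd) || recovery_noise_sd < 0)
    stop("configuration error: recovery_noise_sd must be >= 0",
         call. = FALSE)
  if (n_patients < 1L || n_controls < 1L)
    stop("configuration error: cohort sizes must be >= 1", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 grid_shape = grid_shape,
                 voxel_size = as.numeric(voxel_size),
                 seed = as.integer(seed),
                 prop_severe = prop_severe,
                 prop_cortical = prop_cortical,
                 prop_mep_measured = prop_mep_measured,
                 prop_nonfitted = prop_nonfitted,
                 prop_mep_negative = prop_mep_negative,
                 recovery_noise_sd = recovery_noise_sd,
                 damage_coupling = damage_coupling,
                 n_streamlines_per_control =
                   as.integer(n_streamlines_per_control),
                 prop_background = prop_background,
                 membership_slope = membership_slope,
                 deficit_noise_sd = deficit_noise_sd),
            class = "synthetic_config")
}

derive_seed <- function(seed, stream, i = 0L) {
  as.integer((as.numeric(seed) * 1009 + stream * 7919 + i) %% 2147483647)
}

#' Imaging data of one subject
#'
#' @param lesion_mask binary [volume_grid]; must be nonempty and confined to
#'   the ipsilesional hemisphere (unilateral supratentorial lesion).
#' @param fa_map [volume_grid] with values in \[0, 1\].
#' @param ipsilesional_side `"left"` or `"right"`.
#' @return object of class `imaging_set`.
#' @export
imaging_set <- function(lesion_mask, fa_map, ipsilesional_side) {
  ipsilesional_side <- match.arg(ipsilesional_side, c("left", "right"))
  stopifnot_same_grid(lesion_mask, fa_map)
  if (sum(lesion_mask$values != 0) == 0)
    stop("lesion mask is empty", call. = FALSE)
  contra <- hemisphere_mask(lesion_mask, opposite_side(ipsilesional_side))
  if (any(lesion_mask$values[contra] != 0))
    stop("lesion extends into the contralesional hemisphere", call. = FALSE)
  if (any(fa_map$values < 0) || any(fa_map$values > 1))
    stop("FA values must lie in [0, 1]", call. = FALSE)
  structure(list(lesion_mask = lesion_mask, fa_map = fa_map,
                 ipsilesional_side = ipsilesional_side),
            class = "imaging_set")
}

#' Generate normative-control streamline sets
#'
#' Each control receives `n_streamlines_per_control` streamlines: a dense
#' CST-analogue bundle per hemisphere passing through all three waypoint
#' boxes, plus background fibres, at least one of which crosses the midline
#' whenever background fibres are requested (exercising the contralateral
#' exclusion rule).
#'
#' @param config a [synthetic_config].
#' @return list of [streamline_set], one per control, named `C01`, ...
#' @export
generate_control_streamlines <- function(config) {
  geom <- phantom_geometry(config$grid_shape, config$voxel_size)
  n <- config$n_streamlines_per_control
  lapply(stats::setNames(seq_len(config$n_controls),
                         sprintf("C%02d", seq_len(config$n_controls))),
         function(i) {
           set.seed(derive_seed(config$seed, 2L, i))
           make_streamline_bundle(geom, n, config$prop_background,
                                  source_id = sprintf("C%02d", i))
         })
}

make_streamline_bundle <- function(geom, n, prop_background, source_id) {
  n_back <- round(n * prop_background)
  n_bundle <- n - n_back
  n_left <- ceiling(n_bundle / 2)
  fibres <- c(
    lapply(seq_len(n_left), function(j) bundle_fibre(geom, "left")),
    lapply(seq_len(n_bundle - n_left), function(j)
      bundle_fibre(geom, "right")),
    if (n_back > 0)
      lapply(seq_len(n_back), function(j)
        background_fibre(geom, cross_midline = (j == 1) ||
                           stats::runif(1) < 0.5))
  )
  streamline_set(fibres, source_id = source_id)
}

#' Generate one subject's lesion mask and FA map
#'
#' The lesion is an ellipsoidal blob seeded near the ipsilesional CST
#' corridor; when `record$cortical_flag` is set a second lobe extends the
#' blob into the cortical shell, otherwise the blob is kept out of the
#' shell. The FA map is a smooth field elevated along both CST corridors,
#' with FA reduced inside the lesion and along the ipsilesional corridor in
#' proportion to the lesion--corridor overlap.
#'
#' @param record one-row data frame with at least `subject_id`, `side`
#'   (`"left"`/`"right"`) and `cortical_flag`.
#' @param config a [synthetic_config].
#' @param radius optional lesion base radius in voxels; must be positive and
#'   no larger than the hemisphere half-width.
#' @return an [imaging_set].
#' @export
generate_lesion_and_fa <- function(record, config, radius = NULL) {
  geom <- phantom_geometry(config$grid_shape, config$voxel_size)
  d <- geom$grid_shape
  side <- match.arg(record$side, c("left", "right"))
  hemi_halfwidth <- floor(d[1] / 2) / 2
  if (!is.null(radius)) {
    if (radius <= 0)
      stop("configuration error: lesion radius must be positive",
           call. = FALSE)
    if (radius > hemi_halfwidth)
      stop("configuration error: lesion radius ", radius,
           " exceeds hemisphere half-width ", hemi_halfwidth, call. = FALSE)
  }
  i <- subject_index(record$subject_id)
  set.seed(derive_seed(config$seed, 3L, i))

  cx <- geom$centres[[side]]; cy <- geom$cy; nz <- d[3]
  r <- if (is.null(radius)) stats::runif(1, 1.5, hemi_halfwidth * 0.8)
       else radius
  ctr <- c(cx + stats::rnorm(1, 0, d[1] / 10),
           cy + stats::rnorm(1, 0, d[2] / 10),
           0.5 * nz + stats::rnorm(1, 0, nz / 8))
  xi <- slice.index(array(0, d), 1)
  yi <- slice.index(array(0, d), 2)
  zi <- slice.index(array(0, d), 3)
  mask <- ((xi - ctr[1])^2 + (yi - ctr[2])^2 +
             ((zi - ctr[3]) / 1.4)^2) <= r^2

  shell <- geom$cortical_shell
  if (isTRUE(as.logical(record$cortical_flag))) {
    # second lobe reaching into the cortical shell above the main blob
    top <- c(ctr[1], ctr[2], 0.92 * nz)
    r2 <- max(1.2, r * 0.7)
    lobe <- ((xi - top[1])^2 + (yi - top[2])^2 +
               ((zi - top[3]) / 1.6)^2) <= r2^2
    mask <- mask | lobe
  } else {
    mask[shell] <- FALSE
  }
  hm <- hemisphere_mask(volume_grid(array(0, d), config$voxel_size), side)
  mask <- mask & hm
  if (!any(mask)) {
    # tiny or shell-clipped request: fall back to a single voxel at the
    # corridor centre so the nonempty-lesion invariant holds
    v <- round(c(cx, cy, 0.5 * nz))
    mask[v[1], v[2], v[3]] <- TRUE
    if (isFALSE(as.logical(record$cortical_flag))) mask[shell] <- FALSE
    if (!any(mask))
      stop("configuration error: empty lesion for subject ",
           record$subject_id, call. = FALSE)
  }
  lesion <- volume_grid(mask * 1, config$voxel_size)

  o <- corridor_overlap(lesion, side, geom)
  fa0 <- 0.35 + 0.25 * (geom$corridor$left$values +
                          geom$corridor$right$values)
  fa0 <- fa0 + stats::rnorm(length(fa0), 0, 0.01)
  w_ipsi <- geom$corridor[[side]]$values
  fa <- fa0 * (1 - 0.7 * pmin(1, 5 * o) * w_ipsi)
  fa[mask] <- fa[mask] * 0.25
  fa <- pmin(1, pmax(0, fa))
  imaging_set(lesion, volume_grid(array(fa, d), config$voxel_size), side)
}

subject_index <- function(subject_id) {
  i <- suppressWarnings(as.integer(gsub("[^0-9]", "", subject_id)))
  if (is.na(i)) i <- sum(utf8ToInt(as.character(subject_id))) %% 10000L
  i
}

#' Generate a synthetic cohort
#'
#' Draws demographics, lesion phantoms, FA maps and behavioural scores with
#' the dependence structure the downstream analysis assumes: baseline
#' impairment (2-week UE-FMA) is negatively coupled to the lesion's CST
#' corridor overlap; 3-month outcomes follow the 0.7 proportional recovery
#' rule plus Gaussian noise for fitted subjects, while non-fitted subjects
#' (selected with probability increasing in CST overlap) receive an extra
#' deficit guaranteeing a model residual >= 20; MEP-negative status is
#' likewise more probable at high CST overlap. Scores are integers, clipped
#' to the observed ranges (baseline 4--63, outcome 4--66).
#'
#' @param config a [synthetic_config].
#' @return object of class `synthetic_cohort`: list with `records` (data
#'   frame: subject_id, age, sex, dominance, side, cortical_flag, fma_2w,
#'   fma_3m, mep_status), `imaging` (named list of [imaging_set]),
#'   `patient_streamlines` (named list of [streamline_set]), `cst_overlap`
#'   (the generator's normalised corridor overlaps) and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  n <- config$n_patients
  geom <- phantom_geometry(config$grid_shape, config$voxel_size)

  set.seed(derive_seed(config$seed, 1L))
  ids <- sprintf("P%03d", seq_len(n))
  age <- round(stats::runif(n, 28, 80))
  sex <- stats::rbinom(n, 1, 0.5)
  dominance <- stats::rbinom(n, 1, 27 / 60)
  side <- ifelse(stats::runif(n) < 0.5, "left", "right")
  cortical_flag <- stats::runif(n) < config$prop_cortical
  eps_base <- stats::rnorm(n)

  records <- data.frame(subject_id = ids, age = age, sex = sex,
                        dominance = dominance, side = side,
                        cortical_flag = as.integer(cortical_flag),
                        stringsAsFactors = FALSE)

  imaging <- lapply(seq_len(n), function(i)
    generate_lesion_and_fa(records[i, ], config))
  names(imaging) <- ids
  o <- vapply(seq_len(n), function(i)
    corridor_overlap(imaging[[i]]$lesion_mask, side[i], geom), numeric(1))
  o_scaled <- if (max(o) > 0) o / max(o) else o

  # baseline severity: fma_2w = round(a + z) where z mixes the (negated,
  # standardised) CST overlap with independent noise in proportion
  # damage_coupling : 1, scaled to the observed baseline dispersion
  # (UE-FMA sd 18.2); the intercept a is placed between the order
  # statistics of z so that exactly round(prop_severe * n) subjects score
  # <= 20 before clipping
  u <- if (stats::sd(o_scaled) > 0)
    -(o_scaled - mean(o_scaled)) / stats::sd(o_scaled) else rep(0, n)
  cc <- config$damage_coupling
  z <- 18.2 * (cc * u + eps_base) / sqrt(1 + cc^2)
  m <- round(config$prop_severe * n)
  zs <- sort(z)
  thr <- if (m <= 0) zs[1] - 1
         else if (m >= n) zs[n] + 1
         else (zs[m] + zs[m + 1]) / 2
  a <- 20.5 - thr
  fma_2w <- pmin(63, pmax(4, round(a + z)))

  # recovery failure requires both structural damage and severe initial
  # impairment (mildly impaired patients retain reserve): the membership
  # driver is the CST overlap weighted by a smooth severity ramp, so
  # damage predicts outcome within the severe subgroup while remaining
  # uninformative among the non-severe
  set.seed(derive_seed(config$seed, 4L))
  sev_weight <- stats::plogis((20.5 - fma_2w) / 4)
  nonfitted <- draw_calibrated(o_scaled * sev_weight, config$prop_nonfitted,
                               slope = config$membership_slope)
  pred <- fma_2w + 0.7 * (66 - fma_2w)
  fma_3m <- integer(n)
  for (i in seq_len(n)) {
    if (!nonfitted[i]) {
      fma_3m[i] <- pmin(66, pmax(4, round(
        pred[i] + stats::rnorm(1, 0, config$recovery_noise_sd))))
    } else {
      fma_3m[i] <- draw_nonfitted_outcome(fma_2w[i], pred[i], o_scaled[i],
                                          config)
    }
  }

  set.seed(derive_seed(config$seed, 5L))
  measured <- stats::runif(n) < config$prop_mep_measured
  mep_status <- rep("unmeasured", n)
  if (any(measured)) {
    neg <- draw_calibrated((o_scaled * sev_weight)[measured],
                           config$prop_mep_negative,
                           slope = config$membership_slope)
    mep_status[measured] <- ifelse(neg, "negative", "positive")
  }

  records$fma_2w <- as.integer(fma_2w)
  records$fma_3m <- as.integer(fma_3m)
  records$mep_status <- mep_status

  pat_str <- lapply(seq_len(n), function(i) {
    set.seed(derive_seed(config$seed, 6L, i))
    make_streamline_bundle(geom, config$n_streamlines_per_control,
                           config$prop_background, source_id = ids[i])
  })
  names(pat_str) <- ids

  structure(list(records = records, imaging = imaging,
                 patient_streamlines = pat_str, cst_overlap = o,
                 config = config),
            class = "synthetic_cohort")
}

# Bernoulli draws with per-subject probability increasing in x (logistic
# on standardised x), intercept calibrated so the mean probability equals
# 'target'. The steep default slope makes membership strongly determined
# by structural damage (recovery atypicality and MEP loss track
# corticospinal injury), while remaining stochastic.
draw_calibrated <- function(x, target, slope = 6) {
  n <- length(x)
  if (target <= 0) return(rep(FALSE, n))
  if (target >= 1) return(rep(TRUE, n))
  xs <- if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else rep(0, n)
  alpha <- stats::uniroot(function(a)
    mean(stats::plogis(a + slope * xs)) - target, c(-50, 50))$root
  stats::runif(n) < stats::plogis(alpha + slope * xs)
}

# Outcome of a proportional-recovery non-fitted subject. The deficit
# subtracted from the fitted prediction lies in [20, predicted change] and
# scales with the subject's CST corridor overlap (recovery failure reflects
# structural damage, so outcome remains predictable from the damage
# measures within the non-fitted/severe subgroups). The residual >= 20
# criterion is re-checked on the rounded score, resampling on failure; the
# deterministic fallback floor(pred - 20) always satisfies it.
draw_nonfitted_outcome <- function(f2w, pred, o_scaled, config) {
  hi <- max(20, 0.7 * (66 - f2w))
  for (try in 1:50) {
    g <- pmin(1, pmax(0, o_scaled +
                        stats::rnorm(1, 0, config$deficit_noise_sd)))
    d <- 20 + (hi - 20) * g
    f3m <- pmin(66, pmax(4, round(
      pred - d + stats::rnorm(1, 0, config$recovery_noise_sd / 2))))
    if (0.7 * (66 - f2w) - (f3m - f2w) >= 20) return(as.integer(f3m))
  }
  as.integer(max(4, floor(pred - 20)))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d patients, grid %s, seed %d>\n",
              nrow(x$records),
              paste(x$config$grid_shape, collapse = "x"),
              x$config$seed))
  invisible(x)
}
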