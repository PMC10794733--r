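#' Corticospinal tract territory
#'
#' A weighted tract map: voxel-wise streamline pass-through counts
#' normalised to the maximum count, per hemisphere.
#'
#' @param weight_map [volume_grid] with values in \[0, 1\].
#' @param kind `"patient"` or `"control"`.
#' @return object of class `cst_territory`.
#' @export
cst_territory <- function(weight_map, kind = c("patient", "control")) {
  kind <- match.arg(kind)
  if (any(weight_map$values < 0) || any(weight_map$values > 1))
    stop("territory weights must lie in [0, 1]", call. = FALSE)
  structure(list(weight_map = weight_map, kind = kind),
            class = "cst_territory")
}

#' @export
print.cst_territory <- function(x, ...) {
  cat(sprintf("<cst_territory (%s), %d nonzero voxels>\n", x$kind,
              sum(x$weight_map$values > 0)))
  invisible(x)
}

waypoint_indices <- function(wp) which(wp$values != 0)

check_one_hemisphere <- function(waypoints) {
  grid <- waypoints[[1]]
  hm <- hemisphere_masks(grid)
  for (wp in waypoints) {
    stopifnot_same_grid(grid, wp)
    on_l <- any(wp$values != 0 & hm$left)
    on_r <- any(wp$values != 0 & hm$right)
    if (on_l && on_r)
      stop("waypoint mask spans both hemispheres", call. = FALSE)
  }
  invisible(TRUE)
}

#' Build a one-hemisphere CST territory from streamlines
#'
#' Retains streamlines that intersect all three waypoint masks (precentral
#' gyrus, PLIC and pons analogues; order-free), excluding any that cross
#' the inter-hemispheric midline or enter an optional exclusion zone.
#' Voxel-wise pass-through counts of the retained streamlines are
#' normalised to their maximum.
#'
#' @param set a [streamline_set] or [indexed_streamlines].
#' @param waypoints list of three binary [volume_grid] masks, all within one
#'   hemisphere of a common grid.
#' @param exclusion optional binary [volume_grid]; streamlines entering it
#'   are excluded (cerebellum analogue). Empty by default.
#' @param kind `"patient"` or `"control"` tag on the result.
#' @return a [cst_territory] whose nonzero weights have maximum 1.
#' @export
build_cst_territory <- function(set, waypoints, exclusion = NULL,
                                kind = "patient") {
  if (length(waypoints) != 3L)
    stop("exactly three waypoint masks are required", call. = FALSE)
  check_one_hemisphere(waypoints)
  grid <- waypoints[[1]]
  idx <- as_indexed(set, grid)
  wp_idx <- lapply(waypoints, waypoint_indices)
  excl_idx <- if (!is.null(exclusion)) waypoint_indices(exclusion)
              else integer(0)
  keep <- vapply(seq_along(idx$voxels), function(i) {
    v <- idx$voxels[[i]]
    !idx$crosses_midline[i] &&
      !(length(excl_idx) && any(v %in% excl_idx)) &&
      all(vapply(wp_idx, function(w) any(v %in% w), logical(1)))
  }, logical(1))
  if (!any(keep))
    stop("empty territory: no streamline passes all three waypoints",
         call. = FALSE)
  counts <- count_map(idx$voxels[keep], dim(grid$values))
  cst_territory(volume_grid(counts / max(counts), grid$voxel_size,
                            grid$split_axis),
                kind = kind)
}

#' Bilateral territories
#'
#' `combine_hemispheres` sums two disjoint one-hemisphere territories into a
#' bilateral map (each hemisphere keeps its own maximum of 1).
#' `patient_cst_territory` builds both hemispheres of one subject;
#' `control_cst_territory` averages the bilateral normalised maps over all
#' controls.
#'
#' @param left,right one-hemisphere [cst_territory] objects.
#' @return a [cst_territory].
#' @export
combine_hemispheres <- function(left, right) {
  stopifnot_same_grid(left$weight_map, right$weight_map)
  if (any(left$weight_map$values > 0 & right$weight_map$values > 0))
    stop("hemisphere territories overlap", call. = FALSE)
  g <- left$weight_map
  cst_territory(volume_grid(g$values + right$weight_map$values,
                            g$voxel_size, g$split_axis),
                kind = left$kind)
}

#' @rdname combine_hemispheres
#' @param set a [streamline_set].
#' @param waypoints list with elements `left` and `right`, each a list of
#'   three waypoint masks (as from [phantom_geometry]).
#' @param exclusion optional exclusion-zone mask.
#' @export
patient_cst_territory <- function(set, waypoints, exclusion = NULL) {
  combine_hemispheres(
    build_cst_territory(set, waypoints$left, exclusion, kind = "patient"),
    build_cst_territory(set, waypoints$right, exclusion, kind = "patient"))
}

#' @rdname combine_hemispheres
#' @param sets list of [streamline_set], one per control.
#' @export
control_cst_territory <- function(sets, waypoints, exclusion = NULL) {
  grid <- waypoints$left[[1]]
  acc <- array(0, dim(grid$values))
  for (s in sets) {
    bi <- combine_hemispheres(
      build_cst_territory(s, waypoints$left, exclusion, kind = "control"),
      build_cst_territory(s, waypoints$right, exclusion, kind = "control"))
    acc <- acc + bi$weight_map$values
  }
  cst_territory(volume_grid(acc / length(sets), grid$voxel_size,
                            grid$split_axis),
                kind = "control")
}

#' Structural disconnectome of a lesion
#'
#' For each control, streamlines intersecting any lesion voxel are selected
#' and their voxel-wise pass-through counts normalised to that control's
#' maximum count; the disconnectome is the mean of these normalised maps
#' over controls. A control without any intersecting streamline contributes
#' a zero map; if no control intersects at all, an all-zero map is returned
#' with a warning.
#'
#' @param lesion_mask binary [volume_grid].
#' @param control_sets list of [streamline_set] or [indexed_streamlines].
#' @return [volume_grid] with values in \[0, 1\].
#' @export
build_disconnectome <- function(lesion_mask, control_sets) {
  if (!all(lesion_mask$values %in% c(0, 1)))
    stop("lesion mask must be binary", call. = FALSE)
  les_idx <- which(lesion_mask$values != 0)
  d <- dim(lesion_mask$values)
  acc <- array(0, d)
  any_hit <- FALSE
  for (s in control_sets) {
    idx <- as_indexed(s, lesion_mask)
    hit <- vapply(idx$voxels, function(v) any(v %in% les_idx), logical(1))
    if (any(hit)) {
      counts <- count_map(idx$voxels[hit], d)
      acc <- acc + counts / max(counts)
      any_hit <- TRUE
    }
  }
  if (!any_hit)
    warning("no control streamline intersects the lesion; ",
            "disconnectome is all zero")
  volume_grid(acc / length(control_sets), lesion_mask$voxel_size,
              lesion_mask$split_axis)
}

#' Hemispheric FA asymmetry within a tract territory
#'
#' Computes the territory-weighted mean FA per hemisphere and returns
#' `(FA_contralesional - FA_ipsilesional) / (FA_contralesional +
#' FA_ipsilesional)`. Positive values indicate reduced ipsilesional FA.
#'
#' @param fa_map [volume_grid] of FA values in \[0, 1\].
#' @param territory a [cst_territory] nonempty in both hemispheres.
#' @param ipsilesional_side `"left"` or `"right"`.
#' @param weighted if `TRUE` (default) hemispheric means are weighted by the
#'   territory weights; if `FALSE` the territory is binarised first.
#' @return unitless asymmetry in \[-1, 1\].
#' @export
compute_fa_asymmetry <- function(fa_map, territory,
                                 ipsilesional_side = c("left", "right"),
                                 weighted = TRUE) {
  ipsilesional_side <- match.arg(ipsilesional_side)
  w <- territory$weight_map
  stopifnot_same_grid(fa_map, w)
  wv <- if (weighted) w$values else (w$values > 0) * 1
  hm <- hemisphere_masks(w)
  mean_fa <- function(side) {
    m <- hm[[side]]
    tot <- sum(wv[m])
    if (tot <= 0)
      stop("undefined asymmetry: territory empty in ", side,
           " hemisphere", call. = FALSE)
    sum(wv[m] * fa_map$values[m]) / tot
  }
  ipsi <- mean_fa(ipsilesional_side)
  contra <- mean_fa(opposite_side(ipsilesional_side))
  if (ipsi + contra == 0)
    stop("undefined asymmetry: FA is zero in both hemispheres",
         call. = FALSE)
  (contra - ipsi) / (contra + ipsi)
}

#' Weighted volume of overlap between a damage map and an ROI
#'
#' `sum(damage * roi) * voxel volume`, in cubic millimetres. With a binary
#' damage map and a whole-brain ROI this reduces to the lesion volume.
#'
#' @param damage_map [volume_grid] with values in \[0, 1\] (binary lesion or
#'   weighted disconnectome).
#' @param roi_map [volume_grid] with values in \[0, 1\] (tract weight map or
#'   whole-brain mask).
#' @return weighted volume in mm^3.
#' @export
compute_weighted_overlap <- function(damage_map, roi_map) {
  stopifnot_same_grid(damage_map, roi_map)
  if (any(damage_map$values < 0) || any(damage_map$values > 1))
    stop("damage map values must lie in [0, 1]", call. = FALSE)
  if (any(roi_map$values < 0) || any(roi_map$values > 1))
    stop("ROI values must lie in [0, 1]", call. = FALSE)
  sum(damage_map$values * roi_map$values) * voxel_volume(damage_map)
}

#' All six structural damage measures for one subject
#'
#' Evaluates the full damage-map-by-ROI grid: FA applied to the patient and
#' control CSTs (two asymmetries), lesion and disconnectome applied to the
#' control CST (two loads) and to the whole brain (two volumes).
#'
#' @param imaging an [imaging_set].
#' @param patient_territory bilateral patient [cst_territory].
#' @param control_territory bilateral control [cst_territory].
#' @param control_sets list of control [streamline_set] or
#'   [indexed_streamlines] (for the disconnectome).
#' @param brain_mask optional [volume_grid] whole-brain ROI; defaults to the
#'   full grid.
#' @param weighted_fa passed to [compute_fa_asymmetry].
#' @return object of class `damage_measure_set`: named list with elements
#'   `patient_cst_fa_asym`, `control_cst_fa_asym`, `cst_lesion_load`,
#'   `cst_disconnectome_load`, `lesion_volume`, `disconnectome_volume`
#'   (loads and volumes in weighted mm^3).
#' @export
compute_all_measures <- function(imaging, patient_territory,
                                 control_territory, control_sets,
                                 brain_mask = NULL, weighted_fa = TRUE) {
  lesion <- imaging$lesion_mask
  if (is.null(brain_mask))
    brain_mask <- volume_grid(array(1, dim(lesion$values)),
                              lesion$voxel_size, lesion$split_axis)
  disco <- build_disconnectome(lesion, control_sets)
  out <- list(
    patient_cst_fa_asym = compute_fa_asymmetry(
      imaging$fa_map, patient_territory, imaging$ipsilesional_side,
      weighted = weighted_fa),
    control_cst_fa_asym = compute_fa_asymmetry(
      imaging$fa_map, control_territory, imaging$ipsilesional_side,
      weighted = weighted_fa),
    cst_lesion_load = compute_weighted_overlap(
      lesion, control_territory$weight_map),
    cst_disconnectome_load = compute_weighted_overlap(
      disco, control_territory$weight_map),
    lesion_volume = compute_weighted_overlap(lesion, brain_mask),
    disconnectome_volume = compute_weighted_overlap(disco, brain_mask))
  structure(out, class = "damage_measure_set")
}

#' @export
as.data.frame.damage_measure_set <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Names and codes of the six damage measures
#'
#' @return named character vector mapping the short model codes (PF, CF,
#'   LL, DL, LV, DV) to measure column names.
#' @export
damage_measure_codes <- function() {
  c(PF = "patient_cst_fa_asym", CF = "control_cst_fa_asym",
    LL = "cst_lesion_load", DL = "cst_disconnectome_load",
    LV = "lesion_volume", DV = "disconnectome_volume")
}

#' Partial correlations between damage measures
#'
#' Pearson correlations of measure pairs after linearly removing the
#' covariates (age, sex, hemispheric motor dominance) from each measure; the
#' multicollinearity check applied to the six damage measures. P-values use
#' the t transform with `n - 2 - q` degrees of freedom, `q` the number of
#' covariates; no multiplicity correction.
#'
#' @param measures numeric data frame or matrix, one column per measure.
#' @param covariates numeric data frame or matrix of covariates (same rows).
#' @return list with `estimate` and `p_value` symmetric matrices. Entries
#'   involving a constant (zero-residual-variance) measure are `NA` with a
#'   warning.
#' @export
partial_correlation_matrix <- function(measures, covariates) {
  X <- as.matrix(measures)
  Z <- cbind(1, as.matrix(covariates))
  n <- nrow(X); q <- ncol(Z) - 1L
  if (n <= q + 2L)
    stop("need more subjects than covariates + 2", call. = FALSE)
  res <- stats::lm.fit(Z, X)$residuals
  sds <- apply(res, 2, stats::sd)
  const <- sds < sqrt(.Machine$double.eps) * max(sds, 1)
  if (any(const))
    warning("constant measure column(s) after residualisation: ",
            paste(colnames(X)[const], collapse = ", "),
            "; correlations set to NA")
  r <- suppressWarnings(stats::cor(res))
  r[const, ] <- NA_real_; r[, const] <- NA_real_
  diag(r) <- ifelse(const, NA_real_, 1)
  df <- n - 2L - q
  tval <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  diag(p) <- NA_real_
  list(estimate = r, p_value = p, df = df)
}
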