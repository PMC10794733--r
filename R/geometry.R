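# Phantom geometry shared by the synthetic generator and the tests: a
# vertical corticospinal-tract analogue per hemisphere running from a pons
# box (inferior) through a PLIC box (mid) to a precentral box (superior,
# inside the cortical shell), on a grid whose first axis is left-right.

box_mask <- function(d, xr, yr, zr) {
  a <- array(FALSE, dim = d)
  a[max(1L, xr[1]):min(d[1], xr[2]),
    max(1L, yr[1]):min(d[2], yr[2]),
    max(1L, zr[1]):min(d[3], zr[2])] <- TRUE
  a
}

#' Phantom geometry for a grid
#'
#' Defines, per hemisphere, the three waypoint boxes (precentral-gyrus,
#' posterior-limb-of-internal-capsule and pons analogues) used for
#' corticospinal-tract streamline selection, a cortical shell (top slab of
#' the grid, standing in for cortical grey matter), and a smooth Gaussian
#' corridor weight map around the tract centreline used to couple lesion
#' position to impairment.
#'
#' @param grid_shape integer length-3, all axes >= 8; axis 1 is left-right,
#'   axis 3 inferior-superior.
#' @param voxel_size mm per axis.
#' @return list with per-side waypoint masks (as [volume_grid]s), hemisphere
#'   centres, `cortical_shell` logical array, and `corridor` weight
#'   [volume_grid]s per side.
#' @export
phantom_geometry <- function(grid_shape, voxel_size = c(1, 1, 1)) {
  d <- as.integer(grid_shape)
  if (length(d) != 3L || any(d < 8L))
    stop("grid_shape must have 3 axes, all >= 8", call. = FALSE)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  half <- floor(nx / 2)
  centres <- list(left = (1 + half) / 2, right = (nx - half + 1 + nx) / 2)
  cy <- (ny + 1) / 2

  zr_pons <- c(max(1L, round(0.08 * nz)), round(0.20 * nz))
  zr_plic <- c(round(0.45 * nz), round(0.58 * nz))
  zr_prec <- c(round(0.80 * nz), round(0.92 * nz))
  shell_z0 <- round(0.85 * nz)

  vg <- function(mask) volume_grid(mask * 1, voxel_size = voxel_size)
  side_boxes <- function(cx) {
    wx_wide <- max(1L, round(nx / 10)); wx_narrow <- max(1L, round(nx / 16))
    wy_wide <- max(1L, round(ny / 8));  wy_narrow <- max(1L, round(ny / 10))
    list(
      precentral = vg(box_mask(d, round(cx) + c(-wx_wide, wx_wide),
                               round(cy) + c(-wy_wide, wy_wide), zr_prec)),
      plic = vg(box_mask(d, round(cx) + c(-wx_narrow, wx_narrow),
                         round(cy) + c(-wy_narrow, wy_narrow), zr_plic)),
      pons = vg(box_mask(d, round(cx) + c(-wx_narrow, wx_narrow),
                         round(cy) + c(-wy_narrow, wy_narrow), zr_pons)))
  }

  corridor_map <- function(cx, side) {
    sigma <- nx / 16
    xi <- slice.index(array(0, d), 1)
    yi <- slice.index(array(0, d), 2)
    zi <- slice.index(array(0, d), 3)
    w <- exp(-((xi - cx)^2 + (yi - cy)^2) / (2 * sigma^2))
    w[zi < zr_pons[1] | zi > zr_prec[2]] <- 0
    hm <- hemisphere_masks(volume_grid(array(0, d), voxel_size))
    w[!hm[[side]]] <- 0
    volume_grid(w, voxel_size = voxel_size)
  }

  shell <- array(FALSE, d)
  shell[, , shell_z0:nz] <- TRUE

  list(
    grid_shape = d, voxel_size = voxel_size, centres = centres, cy = cy,
    z_ranges = list(pons = zr_pons, plic = zr_plic, precentral = zr_prec),
    waypoints = list(left = side_boxes(centres$left),
                     right = side_boxes(centres$right)),
    cortical_shell = shell,
    corridor = list(left = corridor_map(centres$left, "left"),
                    right = corridor_map(centres$right, "right"))
  )
}

# Fraction of a hemisphere's corridor weight covered by a lesion; the
# normalised CST overlap driving impairment severity in the generator.
corridor_overlap <- function(lesion_mask, side, geom) {
  w <- geom$corridor[[side]]$values
  tot <- sum(w)
  if (tot <= 0) return(0)
  sum(lesion_mask$values * w) / tot
}

# One bundle fibre through the three waypoint boxes of one hemisphere:
# anchors jittered inside each box, joined by a polyline spanning pons to
# precentral z range.
bundle_fibre <- function(geom, side) {
  cx <- geom$centres[[side]]; cy <- geom$cy
  zr <- geom$z_ranges
  zc <- vapply(zr, mean, numeric(1))
  nx <- geom$grid_shape[1]; ny <- geom$grid_shape[2]
  jit <- function(w) stats::rnorm(3, 0, w / 3)
  wx <- max(1, round(nx / 16)); wy <- max(1, round(ny / 10))
  ax <- pmin(pmax(cx + jit(wx), cx - wx), cx + wx)
  ay <- pmin(pmax(cy + jit(wy), cy - wy), cy + wy)
  z <- c(zr$pons[1], zc[["pons"]], zc[["plic"]], zc[["precentral"]],
         zr$precentral[2])
  x <- c(ax[1], ax[1], ax[2], ax[3], ax[3])
  y <- c(ay[1], ay[1], ay[2], ay[3], ay[3])
  cbind(x, y, z)
}

# A background fibre: a straight polyline between two random points; when
# 'cross_midline', endpoints are forced into opposite hemispheres.
background_fibre <- function(geom, cross_midline = FALSE) {
  d <- geom$grid_shape
  mid <- (d[1] + 1) / 2
  rpt <- function() stats::runif(3, 1, d)
  p1 <- rpt(); p2 <- rpt()
  if (cross_midline) {
    p1[1] <- stats::runif(1, 1, mid - 0.5)
    p2[1] <- stats::runif(1, mid + 0.5, d[1])
  }
  rbind(p1, (p1 + p2) / 2, p2)
}
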