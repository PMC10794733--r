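#' 3D scalar volume on a regular grid
#'
#' A `volume_grid` is a 3D numeric array together with voxel dimensions (mm
#' per axis) and a hemisphere-splitting convention. Grid coordinates are
#' voxel-centre continuous coordinates: voxel `(i, j, k)` is centred at
#' `(i, j, k)` (1-based), so the inter-hemispheric midline along the split
#' axis of length `n` lies at coordinate `(n + 1) / 2`.
#'
#' @param values numeric 3D array.
#' @param voxel_size numeric length-3, voxel edge length in mm per axis;
#'   all entries must be positive.
#' @param split_axis integer in 1..3; the left/right axis. The first axis by
#'   default.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, voxel_size = c(1, 1, 1), split_axis = 1L) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3D array", call. = FALSE)
  if (any(dim(values) < 1L))
    stop("all grid axes must have length >= 1", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("'voxel_size' must be 3 positive lengths (mm)", call. = FALSE)
  split_axis <- as.integer(split_axis)
  if (!split_axis %in% 1:3)
    stop("'split_axis' must be 1, 2 or 3", call. = FALSE)
  structure(list(values = values, voxel_size = voxel_size,
                 split_axis = split_axis),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %s, voxel %s mm, split axis %d>\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$voxel_size), collapse = "x"),
              x$split_axis))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

#' Volume of one voxel in cubic millimetres
#' @param grid a [volume_grid].
#' @return scalar, mm^3.
#' @export
voxel_volume <- function(grid) prod(grid$voxel_size)

stopifnot_same_grid <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      !isTRUE(all.equal(a$voxel_size, b$voxel_size)))
    stop("volumes are on different grids: ",
         paste(dim(a$values), collapse = "x"), " @ ",
         paste(a$voxel_size, collapse = "x"), " mm vs ",
         paste(dim(b$values), collapse = "x"), " @ ",
         paste(b$voxel_size, collapse = "x"), " mm", call. = FALSE)
  invisible(TRUE)
}

#' Hemisphere membership masks
#'
#' Splits the grid at the midline of the split axis. For an odd axis length
#' the midline voxel row belongs to neither hemisphere.
#'
#' @param grid a [volume_grid].
#' @return list with logical arrays `left` and `right` (low- and high-index
#'   side of the split axis) and the continuous `midline` coordinate.
#' @export
hemisphere_masks <- function(grid) {
  d <- dim(grid$values)
  ax <- grid$split_axis
  mid <- (d[ax] + 1) / 2
  idx <- slice.index(grid$values, ax)
  list(left = idx < mid, right = idx > mid, midline = mid)
}

#' Mask of one hemisphere as a logical array
#' @param grid a [volume_grid].
#' @param side `"left"` or `"right"`.
#' @return logical array of `dim(grid)`.
#' @export
hemisphere_mask <- function(grid, side = c("left", "right")) {
  side <- match.arg(side)
  hemisphere_masks(grid)[[side]]
}

#' Mirror side label
#' @param side `"left"` or `"right"`.
#' @return the opposite label.
#' @export
opposite_side <- function(side) {
  side <- match.arg(side, c("left", "right"))
  if (side == "left") "right" else "left"
}

#' Read / write a volume as NIfTI
#'
#' Thin wrappers around \pkg{RNifti}; voxel dimensions are stored in and
#' restored from the NIfTI `pixdim` header field.
#'
#' @param grid a [volume_grid].
#' @param path file path (`.nii` or `.nii.gz`).
#' @param split_axis hemisphere-split convention to attach on read.
#' @return `write_volume` returns `path` invisibly; `read_volume` a
#'   [volume_grid].
#' @export
write_volume <- function(grid, path) {
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, split_axis = 1L) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1:3]
  volume_grid(array(as.numeric(img), dim = dim(img)[1:3]),
              voxel_size = vox, split_axis = split_axis)
}
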