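#' A set of streamlines (polylines in grid space)
#'
#' Streamlines are stored as matrices with one row per point and columns
#' x, y, z in voxel-centre continuous coordinates of a [volume_grid] (so
#' point `(i, j, k)` lies at the centre of voxel `(i, j, k)`).
#'
#' @param streamlines list of numeric matrices, each `m x 3` with `m >= 2`.
#' @param source_id identifier of the subject the set belongs to.
#' @return object of class `streamline_set`.
#' @export
streamline_set <- function(streamlines, source_id = "control") {
  if (!is.list(streamlines))
    stop("'streamlines' must be a list of point matrices", call. = FALSE)
  for (s in streamlines) {
    if (!is.matrix(s) || ncol(s) != 3L || nrow(s) < 2L)
      stop("each streamline must be an m x 3 matrix with m >= 2",
           call. = FALSE)
  }
  structure(list(streamlines = streamlines,
                 source_id = as.character(source_id)),
            class = "streamline_set")
}

#' @export
length.streamline_set <- function(x) length(x$streamlines)

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("<streamline_set '%s', %d streamlines>\n",
              x$source_id, length(x)))
  invisible(x)
}

# Resample a polyline at a fixed arc-length step (in index units) so that
# voxel visits are detected independently of the original point spacing.
resample_polyline <- function(p, step = 0.5) {
  seg <- diff(p)
  len <- sqrt(rowSums(seg^2))
  keep <- len > 0
  if (!any(keep)) return(p[1, , drop = FALSE])
  cum <- c(0, cumsum(len))
  total <- cum[length(cum)]
  t_out <- unique(c(seq(0, total, by = step), total))
  x <- stats::approx(cum, p[, 1], xout = t_out, ties = "ordered")$y
  y <- stats::approx(cum, p[, 2], xout = t_out, ties = "ordered")$y
  z <- stats::approx(cum, p[, 3], xout = t_out, ties = "ordered")$y
  cbind(x, y, z)
}

#' Voxels visited by one streamline
#'
#' A streamline visits a voxel if any point of the polyline, resampled at a
#' half-voxel step along its arc length, rounds to that voxel index. Points
#' falling outside the grid are dropped.
#'
#' @param p `m x 3` point matrix (voxel-centre coordinates).
#' @param grid a [volume_grid].
#' @return integer vector of unique linear voxel indices (1-based).
#' @export
streamline_voxels <- function(p, grid) {
  d <- dim(grid$values)
  q <- round(resample_polyline(p, step = 0.5))
  ok <- q[, 1] >= 1 & q[, 1] <= d[1] &
        q[, 2] >= 1 & q[, 2] <= d[2] &
        q[, 3] >= 1 & q[, 3] <= d[3]
  q <- q[ok, , drop = FALSE]
  if (nrow(q) == 0L) return(integer(0))
  unique(as.integer(q[, 1] + d[1] * (q[, 2] - 1) +
                      d[1] * d[2] * (q[, 3] - 1)))
}

#' Pre-index a streamline set against a grid
#'
#' Computes, once, the visited-voxel list of every streamline plus its
#' midline-crossing status, so that repeated lesion/waypoint queries (e.g.
#' disconnectome construction over many patients) avoid re-rasterising.
#'
#' @param set a [streamline_set].
#' @param grid a [volume_grid] defining resolution and midline.
#' @return object of class `indexed_streamlines`: list with `voxels` (list of
#'   integer index vectors), `crosses_midline` (logical), `source_id`, `dim`.
#' @export
index_streamlines <- function(set, grid) {
  mid <- (dim(grid$values)[grid$split_axis] + 1) / 2
  ax <- grid$split_axis
  vox <- lapply(set$streamlines, streamline_voxels, grid = grid)
  cross <- vapply(set$streamlines, function(p) {
    x <- p[, ax]
    any(x < mid) && any(x > mid)
  }, logical(1))
  structure(list(voxels = vox, crosses_midline = cross,
                 source_id = set$source_id, dim = dim(grid$values)),
            class = "indexed_streamlines")
}

as_indexed <- function(set, grid) {
  if (inherits(set, "indexed_streamlines")) {
    if (!identical(set$dim, dim(grid$values)))
      stop("indexed streamlines were built on a different grid",
           call. = FALSE)
    set
  } else index_streamlines(set, grid)
}

# Voxel-wise count map: number of streamlines (given as voxel-index vectors)
# visiting each voxel, each streamline counted at most once per voxel.
count_map <- function(voxel_lists, d) {
  counts <- numeric(prod(d))
  if (length(voxel_lists)) {
    tab <- tabulate(unlist(voxel_lists, use.names = FALSE), nbins = prod(d))
    counts <- as.numeric(tab)
  }
  array(counts, dim = d)
}

#' Write / read streamline sets as JSON
#'
#' The container is a JSON object `{source_id, streamlines}` where each
#' streamline is an array of `[x, y, z]` points in voxel-centre coordinates.
#'
#' @param set a [streamline_set] (or list of them for `write_streamline_sets`).
#' @param path file path.
#' @return `read_streamlines` returns a [streamline_set].
#' @export
write_streamlines <- function(set, path) {
  obj <- list(source_id = set$source_id,
              streamlines = lapply(set$streamlines, unname))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_streamlines
#' @export
read_streamlines <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sl <- obj$streamlines
  if (is.array(sl) && length(dim(sl)) == 3L) {
    sl <- lapply(seq_len(dim(sl)[1]), function(i) sl[i, , , drop = TRUE])
  }
  sl <- lapply(sl, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  })
  streamline_set(sl, source_id = obj$source_id)
}
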