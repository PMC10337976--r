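#' Volumetric grid with world geometry
#'
#' The universal 3D image carrier: a numeric array (3D, or 4D channel-last)
#' together with per-axis voxel spacing in micrometers and the world
#' coordinate of the center of voxel (0,0,0). Axes are ordered (x, y, z) =
#' left-to-right, posterior-to-anterior, inferior-to-superior; voxel indices
#' are 0-based and refer to voxel centers.
#'
#' @param data 3D (or 4D channel-last) numeric, logical or integer array.
#' @param spacing Numeric length-3 voxel size in micrometers; all > 0.
#' @param origin Numeric length-3 world coordinate (micrometers) of the
#'   center of voxel (0,0,0).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!(length(dim(data)) %in% c(3L, 4L))) {
    stop("`data` must be a 3D or 4D (channel-last) array")
  }
  spacing <- as.numeric(rep_len(spacing, 3L))
  origin <- as.numeric(rep_len(origin, 3L))
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be positive and finite on all axes")
  }
  structure(
    list(data = data, spacing = spacing, origin = origin),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_grid> %s voxels, spacing %s um, origin (%s) um\n",
    paste(d, collapse = "x"),
    paste(signif(x$spacing, 4), collapse = "x"),
    paste(signif(x$origin, 4), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

#' Convert world coordinates to continuous 0-based voxel coordinates
#'
#' @param grid A [voxel_grid].
#' @param pts n x 3 matrix of world coordinates (micrometers).
#' @return n x 3 matrix of continuous 0-based voxel coordinates.
#' @export
world_to_voxel <- function(grid, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3L)
  sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$spacing, "/")
}

#' Convert 0-based voxel coordinates to world coordinates
#'
#' @inheritParams world_to_voxel
#' @param idx n x 3 matrix of (possibly continuous) 0-based voxel coordinates.
#' @return n x 3 matrix of world coordinates in micrometers.
#' @export
voxel_to_world <- function(grid, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  sweep(sweep(idx, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

#' World coordinates of every voxel center
#'
#' @inheritParams world_to_voxel
#' @return n x 3 matrix, rows in array (column-major) order.
#' @export
grid_coordinates <- function(grid) {
  d <- dim(grid$data)[1:3]
  ii <- seq_len(d[1]) - 1
  jj <- seq_len(d[2]) - 1
  kk <- seq_len(d[3]) - 1
  idx <- cbind(
    rep(ii, times = d[2] * d[3]),
    rep(rep(jj, each = d[1]), times = d[3]),
    rep(kk, each = d[1] * d[2])
  )
  voxel_to_world(grid, idx)
}

#' Sample a volume at world coordinates
#'
#' @inheritParams world_to_voxel
#' @param mode `"linear"` (trilinear) or `"nearest"`.
#' @param fill Value returned for samples outside the volume.
#' @return Vector (or matrix for multi-channel volumes) of sampled values.
#' @export
sample_volume <- function(grid, pts, mode = c("linear", "nearest"), fill = 0) {
  mode <- match.arg(mode)
  interp3(grid$data, world_to_voxel(grid, pts), mode = mode, fill = fill)
}

#' Resample a volume through a per-voxel coordinate map
#'
#' Pull-back resampling: output voxel `v` receives the source volume
#' interpolated at the world coordinate `coordmap(v)`. This is the primitive
#' that applies flatmap-stack and warp coordinate fields.
#'
#' @param volume Source [voxel_grid] (3D, or 4D channel-last).
#' @param coordmap A [voxel_grid] whose 4D data holds, per target voxel, the
#'   source world coordinate (last axis length 3, in micrometers). `NA`
#'   entries mark undefined targets and receive `fill`.
#' @param mode `"linear"` or `"nearest"`; `"nearest"` is required for label
#'   volumes (linear interpolation would invent labels).
#' @param fill Fill value for out-of-bounds or undefined targets.
#' @param label Logical; declare the source a label volume. Defaults to
#'   `TRUE` for integer/logical-valued data.
#' @return A [voxel_grid] on the coordmap's grid.
#' @export
resample_with_map <- function(volume, coordmap, mode = c("linear", "nearest"),
                              fill = 0, label = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(volume, "voxel_grid"), inherits(coordmap, "voxel_grid"))
  cd <- dim(coordmap$data)
  if (length(cd) != 4L || cd[4] != 3L) {
    stop("`coordmap` data must be 4D with 3 world-coordinate channels")
  }
  if (is.null(label)) {
    label <- is.logical(volume$data) ||
      (is.numeric(volume$data) && all(volume$data == round(volume$data)) &&
        length(unique(as.vector(volume$data))) <= 32)
  }
  if (label && mode == "linear") {
    stop("linear interpolation on a label volume; use mode = \"nearest\"")
  }
  pts <- matrix(coordmap$data, ncol = 3L)
  vals <- interp3(volume$data, world_to_voxel(volume, pts),
    mode = mode, fill = fill
  )
  d3 <- cd[1:3]
  nch <- if (length(dim(volume$data)) == 4L) dim(volume$data)[4] else 1L
  out <- if (nch == 1L) array(vals, dim = d3) else array(vals, dim = c(d3, nch))
  voxel_grid(out, coordmap$spacing, coordmap$origin)
}

#' Identity coordinate map for a grid
#'
#' @inheritParams world_to_voxel
#' @return A [voxel_grid] coordmap mapping every voxel to its own world
#'   coordinate.
#' @export
identity_coordmap <- function(grid) {
  d <- dim(grid$data)[1:3]
  co <- grid_coordinates(grid)
  voxel_grid(array(co, dim = c(d, 3L)), grid$spacing, grid$origin)
}

#' Default mid-sagittal plane of a grid
#'
#' The world x coordinate of the grid's center, used as the default mirror
#' plane (templates in this pipeline are built left-right symmetric).
#'
#' @inheritParams world_to_voxel
#' @return Scalar world x in micrometers.
#' @export
grid_x_mid <- function(grid) {
  grid$origin[1] + (dim(grid$data)[1] - 1) * grid$spacing[1] / 2
}

#' Mirror an object across the mid-sagittal plane
#'
#' Maps world x to `2 * x_mid - x`. Volumes are resampled onto their own
#' grid; point sets and tractograms have their coordinates reflected.
#' Applying the operation twice is the identity.
#'
#' @param obj A [voxel_grid], [point_set], [tractogram], or n x 3 matrix of
#'   world points.
#' @param x_mid World x of the mirror plane (micrometers); defaults to the
#'   grid's world center for volumes (and must be given for bare point
#'   matrices).
#' @param ... Passed to methods.
#' @return Object of the same kind.
#' @export
mirror_x <- function(obj, x_mid = NULL, ...) UseMethod("mirror_x")

#' @param mode Interpolation mode for volumes (`"linear"` or `"nearest"`;
#'   use `"nearest"` for masks and label volumes).
#' @rdname mirror_x
#' @export
mirror_x.voxel_grid <- function(obj, x_mid = NULL,
                                mode = c("linear", "nearest"), ...) {
  mode <- match.arg(mode)
  if (is.null(x_mid)) x_mid <- grid_x_mid(obj)
  cm <- identity_coordmap(obj)
  d <- dim(cm$data)
  xs <- cm$data[, , , 1]
  cm$data[, , , 1] <- 2 * x_mid - xs
  resample_with_map(obj, cm, mode = mode, label = (mode == "nearest"))
}

#' @rdname mirror_x
#' @export
mirror_x.matrix <- function(obj, x_mid = NULL, ...) {
  if (is.null(x_mid)) stop("`x_mid` must be given for bare point matrices")
  obj[, 1] <- 2 * x_mid - obj[, 1]
  obj
}

#' @rdname mirror_x
#' @export
mirror_x.point_set <- function(obj, x_mid = NULL, ...) {
  if (is.null(x_mid)) stop("`x_mid` must be given for point sets")
  obj$points[, 1] <- 2 * x_mid - obj$points[, 1]
  obj
}

#' @rdname mirror_x
#' @export
mirror_x.tractogram <- function(obj, x_mid = NULL, ...) {
  if (is.null(x_mid)) stop("`x_mid` must be given for tractograms")
  obj$streamlines <- lapply(obj$streamlines, function(s) {
    s[, 1] <- 2 * x_mid - s[, 1]
    s
  })
  obj
}

#' Binary mask on a voxel grid
#'
#' @param grid A [voxel_grid] (values are coerced with `> 0`) or a logical /
#'   0-1 array plus `spacing` and `origin`.
#' @inheritParams voxel_grid
#' @return A [voxel_grid] with 0/1 integer data and class `mask`.
#' @export
as_mask <- function(grid, spacing = NULL, origin = c(0, 0, 0)) {
  if (!inherits(grid, "voxel_grid")) {
    grid <- voxel_grid(grid, spacing, origin)
  }
  grid$data <- array(as.integer(grid$data > 0), dim = dim(grid$data))
  class(grid) <- c("mask", "voxel_grid")
  grid
}

#' Number of foreground voxels in a mask
#'
#' @param mask A mask [voxel_grid].
#' @return Integer voxel count.
#' @export
mask_count <- function(mask) sum(mask$data > 0)

#' Point set in world coordinates
#'
#' @param points n x 3 matrix of world coordinates in micrometers.
#' @param value Optional numeric per-point scalar (probability, intensity).
#' @param label Optional character per-point label.
#' @return An object of class `point_set`.
#' @export
point_set <- function(points, value = NULL, label = NULL) {
  points <- matrix(as.numeric(points), ncol = 3L)
  if (nrow(points) > 0 && any(!is.finite(points))) {
    stop("point coordinates must be finite")
  }
  if (!is.null(value)) stopifnot(length(value) == nrow(points))
  if (!is.null(label)) stopifnot(length(label) == nrow(points))
  structure(list(points = points, value = value, label = label),
    class = "point_set"
  )
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf(
    "<point_set> %d points%s%s\n", nrow(x$points),
    if (!is.null(x$value)) " +value" else "",
    if (!is.null(x$label)) " +label" else ""
  ))
  invisible(x)
}

#' Triangulated mid-surface mesh with flatmap coordinates
#'
#' @param vertices n x 3 world coordinates (micrometers).
#' @param triangles m x 3 1-based vertex indices.
#' @param flat_uv n x 2 per-vertex flatmap coordinates in `[0,1]^2`.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles, flat_uv) {
  vertices <- matrix(as.numeric(vertices), ncol = 3L)
  triangles <- matrix(as.integer(triangles), ncol = 3L)
  flat_uv <- matrix(as.numeric(flat_uv), ncol = 2L)
  if (nrow(flat_uv) != nrow(vertices)) {
    stop("flat_uv must have one row per vertex")
  }
  if (nrow(triangles) > 0 &&
    (min(triangles) < 1L || max(triangles) > nrow(vertices))) {
    stop("triangle indices out of range")
  }
  structure(list(vertices = vertices, triangles = triangles, flat_uv = flat_uv),
    class = "surface_mesh"
  )
}

#' Set of streamlines (polylines) in world coordinates
#'
#' @param streamlines List of k x 3 matrices (k >= 2), world micrometers.
#' @param metadata Optional list of per-streamline metadata.
#' @return An object of class `tractogram`.
#' @export
tractogram <- function(streamlines, metadata = NULL) {
  streamlines <- lapply(streamlines, function(s) matrix(as.numeric(s), ncol = 3L))
  ok <- vapply(
    streamlines,
    function(s) nrow(s) >= 2L && all(is.finite(s)), logical(1)
  )
  if (length(streamlines) > 0 && !all(ok)) {
    stop("every streamline needs >= 2 finite points")
  }
  structure(list(streamlines = streamlines, metadata = metadata),
    class = "tractogram"
  )
}

#' @export
print.tractogram <- function(x, ...) {
  cat(sprintf("<tractogram> %d streamlines\n", length(x$streamlines)))
  invisible(x)
}

#' @export
length.tractogram <- function(x) length(x$streamlines)
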