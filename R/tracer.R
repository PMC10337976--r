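# Injection-site localization, peak-based cell extraction, intensity-based
# tracer segmentation, and density / normalized-intensity map construction.

#' Locate the injection site in the cell-body channel
#'
#' Gaussian-smooths the volume, thresholds at a fraction of the smoothed
#' maximum (default half-maximum), and returns the largest 26-connected
#' component. The injection site appears as the brightest connected
#' structure in the dedicated third channel.
#'
#' @param ch3 A [voxel_grid] (the injection-detail channel).
#' @param sigma Gaussian smoothing scale in micrometers (default: 2 voxels).
#' @param threshold_frac Fraction of the smoothed maximum used as threshold.
#' @return An `injection_site`: `mask` ([voxel_grid]), `centroid` (world
#'   micrometers), `volume_mm3`, `peak` (smoothed maximum used for
#'   thresholding).
#' @export
locate_injection_site <- function(ch3, sigma = NULL, threshold_frac = 0.5) {
  a <- ch3$data
  if (length(dim(a)) == 4L) a <- a[, , , 1]
  if (all(a == 0)) stop("no injection signal: volume is all zero")
  if (is.null(sigma)) sigma <- 2 * min(ch3$spacing)
  sm <- gauss_smooth3(a, sigma / ch3$spacing)
  peak <- max(sm)
  fg <- sm >= threshold_frac * peak
  if (all(fg)) {
    message("locate_injection_site: uniform volume, whole grid is one component (degenerate)")
  }
  lab <- label_components3(fg, 26L)
  mask <- lab == 1L
  idx <- which(mask, arr.ind = TRUE) - 1L
  centroid <- colMeans(voxel_to_world(ch3, idx))
  vol_mm3 <- sum(mask) * prod(ch3$spacing) / 1e9 # um^3 -> mm^3
  structure(
    list(
      mask = as_mask(array(as.integer(mask), dim(mask)), ch3$spacing, ch3$origin),
      centroid = centroid, volume_mm3 = vol_mm3, peak = peak
    ),
    class = "injection_site"
  )
}

#' @export
print.injection_site <- function(x, ...) {
  cat(sprintf(
    "<injection_site> %d voxels (%.3f mm^3), centroid (%s) um\n",
    mask_count(x$mask), x$volume_mm3,
    paste(signif(x$centroid, 4), collapse = ", ")
  ))
  invisible(x)
}

#' Extract cell locations as probability-map peaks
#'
#' Finds local maxima of a probability map that exceed `p_min` (default 0.5,
#' the detection rule for cell-body probability maps), with plateaus of
#' equal probability resolved to their centroid voxel, followed by
#' non-maximum suppression within `min_separation`.
#'
#' @param prob_map A [voxel_grid] with values in `[0, 1]` (2D maps can be
#'   passed as single-slice grids).
#' @param p_min Minimum peak probability.
#' @param min_separation Non-maximum-suppression radius in micrometers
#'   (0 disables suppression).
#' @return A `cell_set`: a [point_set] whose `value` holds peak
#'   probabilities.
#' @export
extract_peaks <- function(prob_map, p_min = 0.5, min_separation = 0) {
  a <- prob_map$data
  if (length(dim(a)) == 4L) a <- a[, , , 1]
  if (min(a) < 0 || max(a) > 1) stop("probability map values must lie in [0, 1]")
  d3 <- dim(a)
  offs <- neighbor_offsets(26L)
  ge_all <- array(TRUE, dim = d3)
  gt_any <- array(FALSE, dim = d3)
  for (r in seq_len(nrow(offs))) {
    nb <- shift3(a, offs[r, ], fill = -Inf)
    ge_all <- ge_all & (a >= nb)
    gt_any <- gt_any | (a > nb)
  }
  cand <- ge_all & (a >= p_min)
  if (!any(cand)) return(point_set(matrix(numeric(0), ncol = 3L), value = numeric(0)))
  # plateau handling: group equal-valued candidate voxels, take the centroid
  lab <- label_components3(cand, 26L)
  ids <- sort(unique(lab[lab > 0]))
  pts <- matrix(0, nrow = length(ids), ncol = 3L)
  val <- numeric(length(ids))
  keep <- logical(length(ids))
  for (i in seq_along(ids)) {
    vox <- which(lab == ids[i], arr.ind = TRUE) - 1L
    vals <- a[lab == ids[i]]
    keep[i] <- any(gt_any[lab == ids[i]])
    pts[i, ] <- colMeans(voxel_to_world(prob_map, vox))
    val[i] <- max(vals)
  }
  pts <- pts[keep, , drop = FALSE]
  val <- val[keep]
  ord <- order(val, decreasing = TRUE)
  pts <- pts[ord, , drop = FALSE]
  val <- val[ord]
  if (min_separation > 0 && nrow(pts) > 1) {
    sel <- logical(nrow(pts))
    for (i in seq_len(nrow(pts))) {
      if (!any(sel)) {
        sel[i] <- TRUE
        next
      }
      d2 <- rowSums(sweep(pts[sel, , drop = FALSE], 2, pts[i, ], "-")^2)
      sel[i] <- min(d2) >= min_separation^2
    }
    pts <- pts[sel, , drop = FALSE]
    val <- val[sel]
  }
  point_set(pts, value = val)
}

#' Threshold-based tracer segmentation
#'
#' Classical stand-in for a learned tracer-probability map: segments voxels
#' where the tracer channel exceeds the background channel by more than
#' `k_sd` background standard deviations. Background statistics are taken
#' outside a dilated injection mask; a one-voxel morphological opening
#' removes isolated voxels.
#'
#' @param ch1,ch2 Background and tracer channels (equal-shape arrays or
#'   [voxel_grid]s).
#' @param k_sd Threshold multiplier on the background standard deviation.
#' @param injection Optional injection mask ([voxel_grid]) to exclude (after
#'   dilation by `dilate` voxels) from background statistics and from the
#'   output.
#' @param dilate Dilation margin in voxels around the injection mask.
#' @param open Logical: apply the one-voxel opening.
#' @return A mask [voxel_grid] of tracer-positive voxels.
#' @export
segment_tracer_by_intensity <- function(ch1, ch2, k_sd = 4, injection = NULL,
                                        dilate = 2L, open = TRUE) {
  g1 <- if (inherits(ch1, "voxel_grid")) ch1 else voxel_grid(ch1, c(1, 1, 1))
  a1 <- g1$data
  a2 <- if (inherits(ch2, "voxel_grid")) ch2$data else ch2
  if (!identical(dim(a1), dim(a2))) stop("channel shapes differ")
  diffim <- a2 - a1
  excl <- array(FALSE, dim = dim(a1))
  if (!is.null(injection)) {
    excl <- dilate_mask(injection$data > 0, dilate)
  }
  bg <- diffim[!excl]
  thr <- mean(bg) + k_sd * stats::sd(bg)
  m <- diffim > thr
  m[excl] <- FALSE
  if (open) m <- open_mask(m)
  as_mask(array(as.integer(m), dim(m)), g1$spacing, g1$origin)
}

#' @noRd
dilate_mask <- function(m, n = 1L) {
  for (i in seq_len(n)) {
    acc <- m
    for (r in seq_len(26)) {
      acc <- acc | shift3(m, neighbor_offsets(26L)[r, ], fill = 0) > 0
    }
    m <- acc
  }
  m
}

# remove isolated foreground voxels (no 26-neighbor in the mask); this is
# the cleanup the intensity segmentation needs without eroding the
# one-voxel-thick fiber structures the tracer produces
#' @noRd
open_mask <- function(m) {
  offs <- neighbor_offsets(26L)
  nb <- array(0, dim = dim(m))
  mm <- array(as.numeric(m), dim = dim(m))
  for (r in seq_len(nrow(offs))) {
    nb <- nb + shift3(mm, offs[r, ], fill = 0)
  }
  m & nb > 0
}

#' Build a tracer density volume from 2D section masks
#'
#' Each output voxel counts the tracer-positive pixels whose centers fall in
#' its in-plane bin (default 50 x 50 micrometers, one output slice per
#' section), so the total positive-pixel count is conserved across binning
#' resolutions.
#'
#' @param section_masks List of 2D 0/1 matrices (one per section).
#' @param pitch Length-2 pixel pitch of the sections in micrometers.
#' @param section_pitch Section-to-section spacing in micrometers (the z
#'   spacing of the output).
#' @param out_spacing In-plane output bin size in micrometers.
#' @return A [voxel_grid] of counts.
#' @export
tracer_density <- function(section_masks, pitch = c(1.385, 1.339),
                           section_pitch = 50, out_spacing = 50) {
  nz <- length(section_masks)
  if (nz == 0L) stop("no sections")
  shp <- dim(section_masks[[1]])
  nx <- max(1L, ceiling(shp[1] * pitch[1] / out_spacing))
  ny <- max(1L, ceiling(shp[2] * pitch[2] / out_spacing))
  out <- array(0, dim = c(nx, ny, nz))
  for (z in seq_len(nz)) {
    m <- section_masks[[z]]
    pos <- which(m > 0, arr.ind = TRUE)
    if (nrow(pos) == 0) next
    # pixel-center world coordinates -> bin indices
    bx <- pmin(nx - 1L, floor((pos[, 1] - 1) * pitch[1] / out_spacing))
    by <- pmin(ny - 1L, floor((pos[, 2] - 1) * pitch[2] / out_spacing))
    tab <- table(1 + bx + nx * by)
    out[, , z][as.integer(names(tab))] <- out[, , z][as.integer(names(tab))] + as.integer(tab)
  }
  voxel_grid(out,
    spacing = c(out_spacing, out_spacing, section_pitch),
    origin = c(out_spacing / 2, out_spacing / 2, 0)
  )
}

#' Normalized tracer signal intensity
#'
#' The tracer intensity is the (non-negative) difference between the tracer
#' and background channels, normalized by its strongest value outside the
#' injection site; the saturated injection site is excluded from the
#' normalization constant, so values inside it may exceed 1 and are not
#' clamped.
#'
#' @param ch1,ch2 Background and tracer channel [voxel_grid]s (co-registered).
#' @param injection Injection mask [voxel_grid] on the same grid.
#' @param dilate Dilation margin (voxels) applied to the injection mask when
#'   searching for the normalization maximum.
#' @return A [voxel_grid] with attribute `norm_constant`.
#' @export
normalized_intensity <- function(ch1, ch2, injection, dilate = 2L) {
  if (!identical(dim(ch1$data), dim(ch2$data))) stop("channel shapes differ")
  diffim <- pmax(ch2$data - ch1$data, 0)
  excl <- dilate_mask(injection$data > 0, dilate)
  norm_c <- max(diffim[!excl])
  if (norm_c <= 0) stop("no tracer signal to normalize outside the injection site")
  out <- voxel_grid(diffim / norm_c, ch1$spacing, ch1$origin)
  attr(out, "norm_constant") <- norm_c
  out
}

#' Voxelwise maximum across normalized tracer maps
#'
#' Combines several normalized tracer images from injections into the same
#' region by taking the voxelwise maximum.
#'
#' @param maps Non-empty list of [voxel_grid]s on identical grids.
#' @return A [voxel_grid].
#' @export
combine_max <- function(maps) {
  if (length(maps) == 0L) stop("no maps")
  ref <- maps[[1]]
  out <- ref$data
  for (m in maps[-1]) {
    if (!identical(dim(m$data), dim(ref$data)) ||
      max(abs(m$spacing - ref$spacing)) > 1e-9 ||
      max(abs(m$origin - ref$origin)) > 1e-9) {
      stop("grids do not match")
    }
    out <- pmax(out, m$data)
  }
  voxel_grid(out, ref$spacing, ref$origin)
}

#' Rasterize a point set into a count volume
#'
#' Builds cell density images: each voxel counts the points inside it, so
#' the total count is conserved (out-of-extent points are dropped with a
#' message). Typical resolutions are 100 and 400 micrometers.
#'
#' @param points A [point_set].
#' @param spacing Isotropic voxel size in micrometers.
#' @param extent 2 x 3 matrix of world min / max corners, or a [voxel_grid]
#'   to copy geometry from.
#' @return A [voxel_grid] of counts.
#' @export
rasterize_points <- function(points, spacing, extent) {
  if (inherits(extent, "voxel_grid")) {
    origin <- extent$origin - extent$spacing / 2 + spacing / 2
    d3 <- as.integer(ceiling(dim(extent$data)[1:3] * extent$spacing / spacing))
  } else {
    origin <- extent[1, ] + spacing / 2
    d3 <- pmax(1L, as.integer(ceiling((extent[2, ] - extent[1, ]) / spacing)))
  }
  spacing <- rep_len(spacing, 3L)
  out <- array(0, dim = d3)
  g <- voxel_grid(out, spacing, origin)
  if (nrow(points$points) > 0) {
    vi <- floor(world_to_voxel(g, points$points) + 0.5)
    ok <- vi[, 1] >= 0 & vi[, 1] < d3[1] & vi[, 2] >= 0 & vi[, 2] < d3[2] &
      vi[, 3] >= 0 & vi[, 3] < d3[3]
    if (any(!ok)) {
      message(sprintf("rasterize_points: %d points outside the extent were dropped", sum(!ok)))
    }
    vi <- vi[ok, , drop = FALSE]
    tab <- table(1 + vi[, 1] + d3[1] * (vi[, 2] + d3[2] * vi[, 3]))
    out[as.integer(names(tab))] <- as.integer(tab)
    g$data <- out
  }
  g
}

#' Label cells as supragranular or infragranular
#'
#' Assigns laminar labels from the cell's relative cortical depth: depth 0
#' is the white-matter side and 1 the pial surface, and cells at or above
#' the `boundary` depth are supragranular. The default boundary 0.5 is a
#' documented surrogate for cortical layer IV.
#'
#' @param cells A [point_set] of cell locations (world micrometers).
#' @param depth_of Function mapping an n x 3 point matrix to relative depths
#'   in `[0, 1]` (`NA` outside the cortex), e.g. built from a flatmap stack.
#' @param boundary Depth fraction standing in for layer IV.
#' @return The [point_set] with `label` set to `"supragranular"`,
#'   `"infragranular"` or `"unassigned"`.
#' @export
classify_laminar <- function(cells, depth_of, boundary = 0.5) {
  if (boundary < 0 || boundary > 1) stop("boundary must lie in [0, 1]")
  d <- depth_of(cells$points)
  lab <- ifelse(is.na(d), "unassigned",
    ifelse(d >= boundary, "supragranular", "infragranular")
  )
  if (any(is.na(d))) {
    message(sprintf("classify_laminar: %d cells outside the cortex left unassigned", sum(is.na(d))))
  }
  cells$label <- lab
  cells
}
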