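# Tractogram symmetrization, mask-based streamline selection, and
# track-density imaging.

#' Mirror-symmetrize a tractogram
#'
#' Returns the original streamlines together with their x-mirrored
#' counterparts, doubling the count; the result is invariant (as a set)
#' under a further mirror.
#'
#' @param t A [tractogram].
#' @param x_mid World x of the mirror plane (micrometers).
#' @return A [tractogram] with `2 * length(t)` streamlines.
#' @export
mirror_tractogram <- function(t, x_mid) {
  m <- mirror_x(t, x_mid = x_mid)
  tractogram(c(t$streamlines, m$streamlines))
}

# 0-based voxel indices visited by a polyline after densification to at
# most `sampling` micrometer steps
#' @noRd
visited_voxels <- function(s, grid, sampling) {
  dense <- densify_polyline(s, sampling)
  vi <- round(world_to_voxel(grid, dense))
  d3 <- dim(grid$data)[1:3]
  ok <- vi[, 1] >= 0 & vi[, 1] < d3[1] & vi[, 2] >= 0 & vi[, 2] < d3[2] &
    vi[, 3] >= 0 & vi[, 3] < d3[3]
  unique(vi[ok, , drop = FALSE])
}

#' Select streamlines touching a mask
#'
#' A streamline is selected iff any point of its polyline, after
#' densification to at most `sampling` micrometer steps along each segment,
#' falls inside a mask voxel (densification prevents tunneling through thin
#' masks). The original geometry is returned.
#'
#' @param t A [tractogram].
#' @param mask A mask [voxel_grid] (e.g. an injection site).
#' @param sampling Densification step in micrometers; at most half the mask
#'   voxel size (default).
#' @return The selected [tractogram] (metadata subset accordingly).
#' @export
select_by_mask <- function(t, mask, sampling = NULL) {
  if (is.null(sampling)) sampling <- min(mask$spacing) / 2
  if (sampling > min(mask$spacing) / 2 + 1e-9) {
    stop("sampling must be at most half the mask voxel size")
  }
  d3 <- dim(mask$data)[1:3]
  sel <- vapply(t$streamlines, function(s) {
    vi <- visited_voxels(s, mask, sampling)
    if (nrow(vi) == 0) return(FALSE)
    lin <- 1 + vi[, 1] + d3[1] * (vi[, 2] + d3[2] * vi[, 3])
    any(mask$data[lin] > 0)
  }, logical(1))
  md <- t$metadata
  if (!is.null(md)) {
    md <- lapply(md, function(f) if (length(f) == length(sel)) f[sel] else f)
  }
  tractogram(t$streamlines[sel], metadata = md)
}

#' Streamline (track) density image
#'
#' Each voxel counts the number of distinct streamlines whose densified
#' path visits it (a streamline contributes at most once per voxel, the
#' track-density imaging convention).
#'
#' @param t A [tractogram].
#' @param grid A [voxel_grid] specifying geometry (data ignored).
#' @param sampling Densification step in micrometers (default half voxel).
#' @return A [voxel_grid] of counts.
#' @export
streamline_density <- function(t, grid, sampling = NULL) {
  if (is.null(sampling)) sampling <- min(grid$spacing) / 2
  d3 <- dim(grid$data)[1:3]
  out <- array(0, dim = d3)
  for (s in t$streamlines) {
    vi <- visited_voxels(s, grid, sampling)
    if (nrow(vi) == 0) next
    lin <- 1 + vi[, 1] + d3[1] * (vi[, 2] + d3[2] * vi[, 3])
    out[lin] <- out[lin] + 1
  }
  voxel_grid(out, grid$spacing, grid$origin)
}
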