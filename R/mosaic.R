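# Tile vignetting correction and section stitching.
#
# The microscope emits overlapping 16-bit tiles with plain-text world
# offsets. A single multiplicative shading (vignette) field is estimated by
# averaging many tiles; tiles are divided by it, cropped at their borders,
# and fused with a linear-ramp blending that forms a partition of unity.

#' Estimate the multiplicative shading (vignette) field
#'
#' Averages a set of image tiles pixelwise (mean or median) and normalizes
#' the result to mean 1. Correcting a tile means dividing it by the field.
#' Shading is estimated per channel by calling this once per channel; the
#' injection-site detail channel is typically excluded from correction
#' because too few of its tiles carry meaningful content.
#'
#' @param tiles Non-empty list of equal-shape 2D matrices.
#' @param robust `"mean"` or `"median"` pixelwise reduction.
#' @return A strictly positive matrix of the tiles' shape with mean 1.
#' @export
estimate_shading <- function(tiles, robust = c("mean", "median")) {
  robust <- match.arg(robust)
  if (length(tiles) == 0L) stop("need at least one tile")
  shp <- dim(tiles[[1]])
  if (!all(vapply(tiles, function(t_) identical(dim(t_), shp), logical(1)))) {
    stop("all tiles must have the same shape")
  }
  if (length(tiles) == 1L) {
    message("estimate_shading: single tile; field is proportional to it (degenerate)")
  }
  st <- matrix(unlist(tiles), nrow = prod(shp))
  field <- if (robust == "mean") {
    matrix(rowMeans(st), shp[1], shp[2])
  } else {
    matrix(apply(st, 1, stats::median), shp[1], shp[2])
  }
  if (any(field <= 0)) stop("shading field has non-positive pixels")
  field / mean(field)
}

#' Correct tiles by a shading field
#'
#' @param tiles List of 2D matrices.
#' @param field Shading field from [estimate_shading()].
#' @return List of corrected tiles (`tile / field`).
#' @export
correct_shading <- function(tiles, field) {
  lapply(tiles, function(t_) t_ / field)
}

#' Stitch tiles into a section image
#'
#' Crops `crop` pixels from every tile boundary, then fuses the tiles on a
#' canvas determined by their world offsets using linear blending: each
#' tile's weight falls linearly from 1 to 0 over `ramp` pixels inside its
#' cropped border, and contributions are normalized so weights sum to one
#' wherever at least one tile contributes.
#'
#' @param tileset A `tile_set` (see [make_tileset()]), or a list with
#'   `tiles`, `offsets` (n x 3 world micrometers), `pitch`.
#' @param crop Pixels cropped from each tile boundary (default 50, the
#'   acquisition protocol's setting); must leave a positive overlap,
#'   i.e. `2 * crop < overlap`.
#' @param blend Blending profile; only `"linear"` is defined.
#' @param ramp Width of the linear ramp in pixels; defaults to the residual
#'   overlap `overlap - 2 * crop`.
#' @return 2D matrix of the stitched section.
#' @export
stitch_tiles <- function(tileset, crop = 50, blend = "linear", ramp = NULL) {
  blend <- match.arg(blend, "linear")
  tiles <- tileset$tiles
  offsets <- tileset$offsets
  pitch <- tileset$pitch
  if (length(tiles) == 0L) stop("empty tile set")
  shp <- dim(tiles[[1]])
  if (2 * crop >= min(shp)) stop("crop removes entire tiles")
  # pixel-grid offsets (tiles are assumed on a common pixel lattice)
  po <- cbind(round(offsets[, 1] / pitch[1]), round(offsets[, 2] / pitch[2]))
  ext <- c(max(po[, 1]) + shp[1], max(po[, 2]) + shp[2]) - c(min(po[, 1]), min(po[, 2]))
  po <- sweep(po, 2, c(min(po[, 1]), min(po[, 2])))
  if (is.null(ramp)) {
    ramp <- if (length(tiles) > 1L) {
      steps <- unique(c(diff(sort(unique(po[, 1]))), diff(sort(unique(po[, 2])))))
      ov <- if (length(steps)) max(0L, shp[1] - min(steps)) else 0L
      max(1L, ov - 2L * crop)
    } else {
      1L
    }
  }
  acc <- matrix(0, ext[1], ext[2])
  wacc <- matrix(0, ext[1], ext[2])
  # per-tile separable weight: linear ramp from the cropped border inward
  wx <- ramp_weights(shp[1], crop, ramp)
  wy <- ramp_weights(shp[2], crop, ramp)
  w_tile <- outer(wx, wy)
  keep_x <- (crop + 1):(shp[1] - crop)
  keep_y <- (crop + 1):(shp[2] - crop)
  for (i in seq_along(tiles)) {
    t_ <- tiles[[i]]
    xs <- po[i, 1] + keep_x
    ys <- po[i, 2] + keep_y
    acc[xs, ys] <- acc[xs, ys] + t_[keep_x, keep_y] * w_tile[keep_x, keep_y]
    wacc[xs, ys] <- wacc[xs, ys] + w_tile[keep_x, keep_y]
  }
  # the canvas border inside the crop margin is never covered: trim it;
  # any interior gap that remains is an error with its bounding box reported
  covered <- wacc > 0
  xs <- which(rowSums(covered) > 0)
  ys <- which(colSums(covered) > 0)
  acc <- acc[min(xs):max(xs), min(ys):max(ys), drop = FALSE]
  wacc <- wacc[min(xs):max(xs), min(ys):max(ys), drop = FALSE]
  covered <- wacc > 0
  if (!all(covered)) {
    hole <- which(!covered, arr.ind = TRUE)
    stop(sprintf(
      "tile offsets leave %d uncovered interior pixels; gap bounding box x[%d,%d] y[%d,%d]",
      nrow(hole), min(hole[, 1]), max(hole[, 1]), min(hole[, 2]), max(hole[, 2])
    ))
  }
  out <- acc / wacc
  attr(out, "offset_px") <- c(min(xs) - 1L, min(ys) - 1L)
  out
}

# separable blending weight along one tile axis: 0 at the cropped border,
# rising linearly over `ramp` pixels, 1 in the interior. Strictly positive
# half a pixel inside the border so the partition of unity has no holes.
#' @noRd
ramp_weights <- function(n, crop, ramp) {
  w <- rep(1, n)
  lo <- crop + 1L
  hi <- n - crop
  r <- max(1L, ramp)
  up <- pmin(1, (seq_len(n) - lo + 0.5) / r)
  down <- pmin(1, (hi - seq_len(n) + 0.5) / r)
  w <- pmin(up, down)
  w[w < 0] <- 0
  w
}

#' Write / read tiles as 16-bit TIFF plus a plain-text offset table
#'
#' The offset table has one line per tile: `path x y z` (world micrometers),
#' mirroring the microscope's plain-text offsets.
#'
#' @param tileset A `tile_set`.
#' @param dir Output directory.
#' @param scale Intensity mapped to the 16-bit ceiling.
#' @return Path of the offset table, invisibly.
#' @export
write_tileset <- function(tileset, dir, scale = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(scale)) scale <- max(vapply(tileset$tiles, max, numeric(1)))
  lines <- character(length(tileset$tiles))
  for (i in seq_along(tileset$tiles)) {
    f <- file.path(dir, sprintf("tile_%04d.tif", i))
    tiff::writeTIFF(pmin(tileset$tiles[[i]] / scale, 1), f, bits.per.sample = 16L)
    lines[i] <- sprintf(
      "%s %.6f %.6f %.6f", basename(f),
      tileset$offsets[i, 1], tileset$offsets[i, 2], tileset$offsets[i, 3]
    )
  }
  tab <- file.path(dir, "offsets.txt")
  writeLines(c(
    sprintf("# pitch %.6f %.6f", tileset$pitch[1], tileset$pitch[2]),
    sprintf("# scale %.9g", scale), lines
  ), tab)
  invisible(tab)
}

#' @rdname write_tileset
#' @param table_path Path to an offset table written by [write_tileset()].
#' @export
read_tileset <- function(table_path) {
  lines <- readLines(table_path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  pitch <- as.numeric(strsplit(sub("# pitch ", "", hdr[1]), " ")[[1]])
  scale <- as.numeric(sub("# scale ", "", hdr[2]))
  dir <- dirname(table_path)
  tiles <- list()
  offsets <- NULL
  for (ln in body) {
    parts <- strsplit(ln, " +")[[1]]
    tiles[[length(tiles) + 1L]] <- tiff::readTIFF(file.path(dir, parts[1])) * scale
    offsets <- rbind(offsets, as.numeric(parts[2:4]))
  }
  structure(
    list(
      tiles = tiles, offsets = offsets, pitch = pitch,
      tile_size = dim(tiles[[1]]), overlap = NA_integer_
    ),
    class = "tile_set"
  )
}
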