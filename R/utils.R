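# Internal vectorized array primitives shared across modules.
# All voxel indices are 0-based and refer to voxel centers; arrays are
# indexed [x, y, z] (or [x, y, z, channel] for multi-channel volumes).

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Shift a 3D array by an integer offset, filling vacated voxels with `fill`.
#' @noRd
shift3 <- function(a, off, fill = NA_real_) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= d[ax] || -o >= d[ax]) return(out)
    if (o >= 0) {
      dst[[ax]] <- seq.int(1L + o, d[ax])
      src[[ax]] <- seq.int(1L, d[ax] - o)
    } else {
      dst[[ax]] <- seq.int(1L, d[ax] + o)
      src[[ax]] <- seq.int(1L - o, d[ax])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Offsets of the 6- or 26-neighborhood (excluding the center).
#' @noRd
neighbor_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
  g
}

# Separable Gaussian smoothing of a 3D array with per-axis sigma in voxels.
# Uses normalized convolution so edges are not dimmed.
#' @noRd
gauss_smooth3 <- function(a, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  num <- a
  den <- array(1, dim = dim(a))
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- exp(-(seq(-r, r))^2 / (2 * s^2))
    n2 <- array(0, dim = dim(a))
    d2 <- array(0, dim = dim(a))
    for (k in seq_along(w)) {
      off <- c(0L, 0L, 0L)
      off[ax] <- k - r - 1L
      n2 <- n2 + w[k] * shift3(num, off, fill = 0)
      d2 <- d2 + w[k] * shift3(den, off, fill = 0)
    }
    num <- n2
    den <- d2
  }
  num / den
}

# Label connected components of a binary 3D array (26- or 6-connectivity)
# by iterated minimum-label propagation restricted to the mask bounding box.
# Returns an integer array; 0 = background, components numbered 1..k by
# decreasing voxel count.
#' @noRd
label_components3 <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  m <- mask > 0
  out <- array(0L, dim = d)
  if (!any(m)) return(out)
  idx <- which(m, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, d)
  sub <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  if (length(dim(sub)) < 3L) dim(sub) <- hi - lo + 1L
  lab <- array(Inf, dim = dim(sub))
  lab[sub] <- which(sub)
  offs <- neighbor_offsets(connectivity)
  repeat {
    new <- lab
    for (r in seq_len(nrow(offs))) {
      new <- pmin(new, shift3(lab, offs[r, ], fill = Inf))
    }
    new[!sub] <- Inf
    if (all(new[sub] == lab[sub])) break
    lab <- new
  }
  ids <- sort(unique(lab[sub]))
  relab <- array(0L, dim = dim(sub))
  relab[sub] <- match(lab[sub], ids)
  counts <- tabulate(relab[sub])
  ord <- order(counts, decreasing = TRUE)
  rank <- integer(length(ord))
  rank[ord] <- seq_along(ord)
  relab[sub] <- rank[relab[sub]]
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- relab
  out
}

# Interpolate a 3D (or 4D channel-last) array at continuous 0-based voxel
# coordinates. `idx` is an n x 3 matrix. Out-of-bounds samples get `fill`;
# rows with any NA get `fill`; non-finite (NaN/Inf) rows raise an error.
# Near-integer coordinates are snapped so that exact-grid lookups are exact.
#' @noRd
interp3 <- function(arr, idx, mode = c("linear", "nearest"), fill = 0) {
  mode <- match.arg(mode)
  d <- dim(arr)
  nch <- if (length(d) == 4L) d[4] else 1L
  d3 <- d[1:3]
  idx <- matrix(as.numeric(idx), ncol = 3L)
  n <- nrow(idx)
  undef <- rowSums(is.na(idx)) > 0
  if (any(is.nan(idx) | is.infinite(idx))) {
    stop("coordinate map contains non-finite (NaN/Inf) entries")
  }
  out <- matrix(fill, nrow = n, ncol = nch)
  ok <- !undef
  if (mode == "nearest") {
    pi_ <- round(idx)
    inb <- ok & pi_[, 1] >= 0 & pi_[, 1] <= d3[1] - 1 &
      pi_[, 2] >= 0 & pi_[, 2] <= d3[2] - 1 &
      pi_[, 3] >= 0 & pi_[, 3] <= d3[3] - 1
    if (any(inb)) {
      lin <- 1 + pi_[inb, 1] + d3[1] * (pi_[inb, 2] + d3[2] * pi_[inb, 3])
      for (c_ in seq_len(nch)) {
        base <- (c_ - 1) * prod(d3)
        out[inb, c_] <- arr[lin + base]
      }
    }
  } else {
    # snap to grid to make identity maps lossless
    snap <- which(abs(idx - round(idx)) < 1e-7)
    idx[snap] <- round(idx[snap])
    f0 <- floor(idx)
    fr <- idx - f0
    inb <- ok & f0[, 1] >= -1 & f0[, 1] <= d3[1] - 1 &
      f0[, 2] >= -1 & f0[, 2] <= d3[2] - 1 &
      f0[, 3] >= -1 & f0[, 3] <= d3[3] - 1
    # allow exact upper-edge and treat fully-out as fill
    if (any(inb)) {
      f0i <- f0[inb, , drop = FALSE]
      fri <- fr[inb, , drop = FALSE]
      acc <- matrix(0, nrow = sum(inb), ncol = nch)
      for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
        w <- (if (cx == 1) fri[, 1] else 1 - fri[, 1]) *
          (if (cy == 1) fri[, 2] else 1 - fri[, 2]) *
          (if (cz == 1) fri[, 3] else 1 - fri[, 3])
        use <- w > 0
        if (!any(use)) next
        xi <- f0i[use, 1] + cx
        yi <- f0i[use, 2] + cy
        zi <- f0i[use, 3] + cz
        vin <- xi >= 0 & xi <= d3[1] - 1 & yi >= 0 & yi <= d3[2] - 1 &
          zi >= 0 & zi <= d3[3] - 1
        val <- matrix(fill, nrow = sum(use), ncol = nch)
        if (any(vin)) {
          lin <- 1 + xi[vin] + d3[1] * (yi[vin] + d3[2] * zi[vin])
          for (c_ in seq_len(nch)) {
            base <- (c_ - 1) * prod(d3)
            val[vin, c_] <- arr[lin + base]
          }
        }
        acc[use, ] <- acc[use, ] + w[use] * val
      }
      out[inb, ] <- acc
    }
  }
  if (nch == 1L) drop(out) else out
}

# Deterministic near-uniform points on the unit sphere (Fibonacci lattice).
#' @noRd
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Random rotation matrix from a seed-driven RNG stream.
#' @noRd
random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr(m)
  r <- qr.Q(q)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

#' @noRd
normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}
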