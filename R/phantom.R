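# Synthetic phantoms with analytic ground truth for every pipeline stage.
# The shell cortex stands in for a real hemisphere: a spherical shell sector
# whose depth and flatmap coordinates have closed forms, so the flatmap-stack
# machinery can be scored against exact oracles.

#' Cortex model: masks plus flat-mapped mid-surface
#'
#' @param interior Interior cortex mask ([voxel_grid] of 0/1).
#' @param inner_boundary,outer_boundary One-voxel-thick boundary masks
#'   (white-matter side / pial side) on the same grid.
#' @param mid_surface A [surface_mesh] with per-vertex `flat_uv`.
#' @return An object of class `cortex_model`.
#' @export
cortex_model <- function(interior, inner_boundary, outer_boundary, mid_surface) {
  structure(
    list(
      interior = interior, inner_boundary = inner_boundary,
      outer_boundary = outer_boundary, mid_surface = mid_surface
    ),
    class = "cortex_model"
  )
}

# split the one-voxel-thick boundary of `interior` into inner/outer/lateral
# using a per-voxel scalar that increases from the inner to the outer side.
#' @noRd
split_boundaries <- function(interior, inner_out, outer_out) {
  offs <- neighbor_offsets(6L)
  inner <- outer <- array(FALSE, dim = dim(interior))
  for (r in seq_len(nrow(offs))) {
    nb_out_inner <- shift3(inner_out, offs[r, ], fill = 0) > 0
    nb_out_outer <- shift3(outer_out, offs[r, ], fill = 0) > 0
    inner <- inner | (interior & nb_out_inner)
    outer <- outer | (interior & nb_out_outer)
  }
  outer[inner] <- FALSE # corners: inner label wins, keeps sets disjoint
  list(inner = inner, outer = outer)
}

#' Spherical-shell cortex phantom with analytic depth and flatmap
#'
#' Rasterizes a shell sector (a "cortex" between radii `r_inner` and
#' `r_outer`, restricted to an angular patch that excludes the poles) onto a
#' voxel grid, builds the mid-surface mesh at radius `(r_inner + r_outer)/2`
#' with the equirectangular flatmap rescaled to `[0,1]^2`, and returns
#' closed-form depth and flatmap functions for scoring.
#'
#' @param r_inner,r_outer Shell radii in micrometers, `0 < r_inner < r_outer`.
#' @param spacing Isotropic voxel size in micrometers; must be at most
#'   `(r_outer - r_inner) / 4` so the shell is rasterizable.
#' @param patch Angular extents in radians,
#'   `c(lon_min, lon_max, lat_min, lat_max)`; must stay >= 10 degrees away
#'   from the poles. Default is a 120 x 120 degree patch facing +x.
#' @param mesh_density Mid-surface mesh vertices per steradian.
#' @param center World center of the shell (micrometers).
#' @return An object of class `cortex_truth`: fields `cortex`
#'   ([cortex_model]), `depth_fn(pts)`, `flat_fn(pts)`, `r_inner`, `r_outer`,
#'   `center`, `patch`, `thickness`.
#' @export
make_shell_cortex <- function(r_inner = 1000, r_outer = 2000, spacing = 50,
                              patch = c(-pi / 3, pi / 3, -pi / 3, pi / 3),
                              mesh_density = 600, center = c(0, 0, 0)) {
  stopifnot(r_inner > 0, r_outer > r_inner)
  if (spacing > (r_outer - r_inner) / 4) {
    stop("spacing too coarse: shell would be under 4 voxels thick")
  }
  if (patch[3] < -(pi / 2 - pi / 18) || patch[4] > (pi / 2 - pi / 18)) {
    stop("patch must exclude the poles by at least 10 degrees")
  }
  lon0 <- patch[1]; lon1 <- patch[2]; lat0 <- patch[3]; lat1 <- patch[4]

  # bounding box from a dense sample of the patch at both radii
  gl <- seq(lon0, lon1, length.out = 60)
  gb <- seq(lat0, lat1, length.out = 60)
  ang <- expand.grid(lon = gl, lat = gb)
  dirs <- cbind(
    cos(ang$lat) * cos(ang$lon),
    cos(ang$lat) * sin(ang$lon),
    sin(ang$lat)
  )
  pts <- rbind(r_inner * dirs, r_outer * dirs)
  lo <- apply(pts, 2, min) - 3 * spacing + center
  hi <- apply(pts, 2, max) + 3 * spacing + center
  d3 <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  origin <- lo

  co <- grid_coordinates(voxel_grid(array(0, d3), spacing, origin))
  rel <- sweep(co, 2, center, "-")
  r <- sqrt(rowSums(rel^2))
  lon <- atan2(rel[, 2], rel[, 1])
  lat <- asin(pmin(1, pmax(-1, rel[, 3] / pmax(r, 1e-12))))
  in_shell <- r >= r_inner & r <= r_outer
  in_patch <- lon >= lon0 & lon <= lon1 & lat >= lat0 & lat <= lat1
  interior <- array(in_shell & in_patch, dim = d3)
  r_arr <- array(r, dim = d3)
  lon_arr <- array(lon, dim = d3)
  lat_arr <- array(lat, dim = d3)
  below <- (!interior) & r_arr < r_inner &
    lon_arr >= lon0 & lon_arr <= lon1 & lat_arr >= lat0 & lat_arr <= lat1
  above <- (!interior) & r_arr > r_outer &
    lon_arr >= lon0 & lon_arr <= lon1 & lat_arr >= lat0 & lat_arr <= lat1
  bnd <- split_boundaries(interior, below, above)

  # mid-surface mesh: regular grid in (lon, lat) at the mid radius
  area_sr <- (lon1 - lon0) * (sin(lat1) - sin(lat0))
  n_total <- max(16L, round(mesh_density * area_sr))
  n_lat <- max(4L, round(sqrt(n_total * (lat1 - lat0) / (lon1 - lon0))))
  n_lon <- max(4L, ceiling(n_total / n_lat))
  ml <- seq(lon0, lon1, length.out = n_lon)
  mb <- seq(lat0, lat1, length.out = n_lat)
  mg <- expand.grid(lon = ml, lat = mb)
  r_mid <- (r_inner + r_outer) / 2
  verts <- cbind(
    r_mid * cos(mg$lat) * cos(mg$lon),
    r_mid * cos(mg$lat) * sin(mg$lon),
    r_mid * sin(mg$lat)
  )
  verts <- sweep(verts, 2, center, "+")
  uv <- cbind((mg$lon - lon0) / (lon1 - lon0), (mg$lat - lat0) / (lat1 - lat0))
  tri <- grid_triangles(n_lon, n_lat)
  mesh <- surface_mesh(verts, tri, uv)

  depth_fn <- function(p) {
    p <- matrix(as.numeric(p), ncol = 3L)
    rr <- sqrt(rowSums(sweep(p, 2, center, "-")^2))
    (rr - r_inner) / (r_outer - r_inner)
  }
  flat_fn <- function(p) {
    p <- matrix(as.numeric(p), ncol = 3L)
    q <- sweep(p, 2, center, "-")
    rr <- sqrt(rowSums(q^2))
    lo_ <- atan2(q[, 2], q[, 1])
    la_ <- asin(pmin(1, pmax(-1, q[, 3] / pmax(rr, 1e-12))))
    cbind((lo_ - lon0) / (lon1 - lon0), (la_ - lat0) / (lat1 - lat0))
  }

  structure(
    list(
      cortex = cortex_model(
        interior = as_mask(array(as.integer(interior), d3), spacing, origin),
        inner_boundary = as_mask(array(as.integer(bnd$inner), d3), spacing, origin),
        outer_boundary = as_mask(array(as.integer(bnd$outer), d3), spacing, origin),
        mid_surface = mesh
      ),
      depth_fn = depth_fn, flat_fn = flat_fn,
      r_inner = r_inner, r_outer = r_outer, center = center,
      patch = patch, thickness = r_outer - r_inner
    ),
    class = "cortex_truth"
  )
}

# triangles of a regular n_u x n_v vertex grid (vertex id = u + n_u*(v-1))
#' @noRd
grid_triangles <- function(n_u, n_v) {
  iu <- rep(seq_len(n_u - 1L), times = n_v - 1L)
  iv <- rep(seq_len(n_v - 1L), each = n_u - 1L)
  a <- iu + n_u * (iv - 1L)
  b <- a + 1L
  c_ <- a + n_u
  d_ <- c_ + 1L
  rbind(cbind(a, b, d_), cbind(a, d_, c_))
}

#' Flat-slab cortex phantom
#'
#' A rectangular slab between two parallel planes: depth is linear in z and
#' the flatmap is the scaled (x, y) position. Used for tests where symmetry
#' forces a constant direction field and a near-isometric flatmap stack.
#'
#' @param thickness Slab thickness (z extent of the cortex) in micrometers.
#' @param extent Length-2 in-plane world extent (x, y) in micrometers.
#' @param spacing Isotropic voxel size in micrometers.
#' @return A `cortex_truth` object (see [make_shell_cortex()]).
#' @export
make_slab_cortex <- function(thickness = 1000, extent = c(3000, 3000),
                             spacing = 50) {
  if (spacing > thickness / 4) stop("spacing too coarse for slab thickness")
  nx <- as.integer(ceiling(extent[1] / spacing)) + 1L
  ny <- as.integer(ceiling(extent[2] / spacing)) + 1L
  nz <- as.integer(ceiling(thickness / spacing)) + 1L
  d3 <- c(nx, ny, nz + 6L) # z margin outside the slab
  origin <- c(0, 0, -3 * spacing)
  co <- grid_coordinates(voxel_grid(array(0, d3), spacing, origin))
  z <- co[, 3]
  interior <- array(z >= 0 & z <= thickness, dim = d3)
  below <- array(z < 0, dim = d3)
  above <- array(z > thickness, dim = d3)
  bnd <- split_boundaries(interior, below, above)

  n_u <- max(8L, round(extent[1] / (2 * spacing)))
  n_v <- max(8L, round(extent[2] / (2 * spacing)))
  gx <- seq(0, extent[1], length.out = n_u)
  gy <- seq(0, extent[2], length.out = n_v)
  mg <- expand.grid(x = gx, y = gy)
  verts <- cbind(mg$x, mg$y, thickness / 2)
  uv <- cbind(mg$x / extent[1], mg$y / extent[2])
  mesh <- surface_mesh(verts, grid_triangles(n_u, n_v), uv)

  depth_fn <- function(p) {
    p <- matrix(as.numeric(p), ncol = 3L)
    p[, 3] / thickness
  }
  flat_fn <- function(p) {
    p <- matrix(as.numeric(p), ncol = 3L)
    cbind(p[, 1] / extent[1], p[, 2] / extent[2])
  }

  structure(
    list(
      cortex = cortex_model(
        interior = as_mask(array(as.integer(interior), d3), spacing, origin),
        inner_boundary = as_mask(array(as.integer(bnd$inner), d3), spacing, origin),
        outer_boundary = as_mask(array(as.integer(bnd$outer), d3), spacing, origin),
        mid_surface = mesh
      ),
      depth_fn = depth_fn, flat_fn = flat_fn,
      r_inner = NULL, r_outer = NULL, center = NULL,
      patch = NULL, thickness = thickness
    ),
    class = "cortex_truth"
  )
}

#' Three-channel STPT-like phantom with injection, tracer and cells
#'
#' Emulates the acquisition geometry of two-photon tomography stacks:
#' channel 1 is the auto-fluorescent background (plus a weak tracer
#' bleed-through), channel 2 adds the bright tracer fibers and a saturated
#' injection blob, and channel 3 is near zero outside the injection site with
#' bright Gaussian spots at the infected cell bodies inside it. Ground-truth
#' structures (injection mask, tracer mask, cell centers) are returned for
#' scoring.
#'
#' @param cortex A `cortex_truth` (supplies the voxel grid), or `NULL` to use
#'   a bare box grid of dimensions `dim`.
#' @param injection List with `center` (world micrometers) and `radius`
#'   (micrometers); the sphere must lie inside the grid.
#' @param n_fibers Number of tracer fiber polylines emanating from the
#'   injection center (`>= 0`).
#' @param n_cells Number of planted cell bodies inside the injection site.
#' @param noise_sd Multiplicative Gaussian noise fraction (clipped at 0).
#' @param seed Integer RNG seed; fixed seed gives a bitwise-identical phantom.
#' @param dim Grid dimensions when `cortex` is `NULL`.
#' @param spacing Voxel spacing when `cortex` is `NULL`.
#' @return List with `channels` (a 4D [voxel_grid], 3 channels) and `truth`
#'   (injection mask, tracer mask, `cells` [point_set], intensity constants).
#' @export
make_stpt_phantom <- function(cortex = NULL, injection, n_fibers = 12,
                              n_cells = 40, noise_sd = 0.02, seed = 1,
                              dim = c(64, 64, 64), spacing = 50) {
  if (n_fibers < 0) stop("n_fibers must be >= 0")
  if (!is.null(cortex)) {
    grid0 <- cortex$cortex$interior
    d3 <- dim(grid0$data)[1:3]
    spacing <- grid0$spacing
    origin <- grid0$origin
  } else {
    d3 <- dim
    spacing <- rep_len(spacing, 3L)
    origin <- c(0, 0, 0)
  }
  set.seed(seed)
  bg_level <- 100
  sat_level <- 2000
  fiber_level <- 400
  cell_level <- 1000

  co <- grid_coordinates(voxel_grid(array(0, d3), spacing, origin))
  rel <- sweep(co, 2, injection$center, "-")
  rinj <- sqrt(rowSums(rel^2))
  inj_mask <- array(rinj <= injection$radius, dim = d3)
  if (!any(inj_mask)) stop("injection sphere does not intersect the grid")

  # smooth background: coarse random field upsampled by heavy smoothing
  coarse <- array(stats::rnorm(prod(d3)), dim = d3)
  bg <- bg_level * (1 + 0.2 * gauss_smooth3(coarse, 4) /
    stats::sd(gauss_smooth3(coarse, 4)) * 0.5)

  # tracer fibers: straight polylines from the injection center
  tracer <- array(0, dim = d3)
  tracer_mask <- array(FALSE, dim = d3)
  if (n_fibers > 0) {
    dirs <- normalize_rows(matrix(stats::rnorm(3 * n_fibers), ncol = 3L))
    ext <- (d3 - 1) * spacing
    L <- 0.45 * min(ext)
    step <- min(spacing) / 2.5
    tt <- seq(0, L, by = step)
    for (f in seq_len(n_fibers)) {
      pts <- sweep(outer(tt, dirs[f, ]), 2, injection$center, "+")
      vi <- round(world_to_voxel(voxel_grid(array(0, d3), spacing, origin), pts))
      ok <- vi[, 1] >= 0 & vi[, 1] < d3[1] & vi[, 2] >= 0 & vi[, 2] < d3[2] &
        vi[, 3] >= 0 & vi[, 3] < d3[3]
      vi <- vi[ok, , drop = FALSE]
      lin <- 1 + vi[, 1] + d3[1] * (vi[, 2] + d3[2] * vi[, 3])
      tracer[lin] <- fiber_level
      tracer_mask[lin] <- TRUE
    }
    tracer_mask[inj_mask] <- FALSE
  }

  # cells: planted at voxel centers inside 0.75 * radius, min 3-voxel spacing
  cand <- which(array(rinj <= 0.75 * injection$radius, dim = d3))
  cand <- sample(cand)
  sel <- integer(0)
  sep2 <- (3 * min(spacing))^2
  cand_xyz <- co[cand, , drop = FALSE]
  for (i in seq_along(cand)) {
    if (length(sel) >= n_cells) break
    p <- cand_xyz[i, ]
    if (length(sel) == 0 ||
      min(rowSums(sweep(cand_xyz[sel, , drop = FALSE], 2, p, "-")^2)) > sep2) {
      sel <- c(sel, i)
    }
  }
  cells_xyz <- cand_xyz[sel, , drop = FALSE]

  ch3 <- array(0, dim = d3)
  ch3[inj_mask] <- 0.5 * cell_level
  # Gaussian spots (sigma = 1 voxel) centered exactly on cell voxels
  if (nrow(cells_xyz) > 0) {
    spot <- array(0, dim = d3)
    vi <- round(world_to_voxel(voxel_grid(array(0, d3), spacing, origin), cells_xyz))
    lin <- 1 + vi[, 1] + d3[1] * (vi[, 2] + d3[2] * vi[, 3])
    spot[lin] <- 1
    spot <- gauss_smooth3(spot, 1)
    ch3 <- ch3 + cell_level * spot / max(spot)
  }

  ch1 <- bg + 0.1 * tracer
  ch2 <- bg + tracer
  ch2[inj_mask] <- sat_level

  noisy <- function(a) {
    if (noise_sd <= 0) return(a)
    array(pmax(a * (1 + noise_sd * stats::rnorm(prod(d3))), 0), dim = d3)
  }
  channels <- array(0, dim = c(d3, 3L))
  channels[, , , 1] <- noisy(ch1)
  channels[, , , 2] <- noisy(ch2)
  channels[, , , 3] <- noisy(ch3)

  list(
    channels = voxel_grid(channels, spacing, origin),
    truth = list(
      injection = as_mask(array(as.integer(inj_mask), d3), spacing, origin),
      tracer = as_mask(array(as.integer(tracer_mask), d3), spacing, origin),
      cells = point_set(cells_xyz),
      levels = c(
        background = bg_level, fiber = fiber_level,
        cell = cell_level, saturation = sat_level
      ),
      noise_sd = noise_sd
    )
  )
}

#' Cut a 2D section image into overlapping vignetted tiles
#'
#' Covers the image with tiles of `tile_size` pixels overlapping by
#' `overlap` pixels (the acquisition default is 720-pixel tiles with about
#' an 80-pixel overlap), multiplies each tile by the vignette field and by
#' multiplicative noise, and records the world offset of each tile.
#'
#' @param image 2D numeric matrix (one channel of a section).
#' @param tile_size Tile side in pixels.
#' @param overlap Overlap between adjacent tiles in pixels
#'   (`< tile_size / 2`).
#' @param vignette `tile_size` x `tile_size` strictly positive multiplicative
#'   field, or `NULL` for a flat field.
#' @param noise_sd Multiplicative Gaussian noise fraction.
#' @param seed Integer RNG seed.
#' @param pitch Length-2 pixel pitch in micrometers per pixel (x, y).
#' @return A `tile_set`: `tiles` (list of matrices), `offsets` (n x 3 world
#'   micrometers of each tile's pixel (0,0) center), `pitch`, `tile_size`,
#'   `overlap`.
#' @export
make_tileset <- function(image, tile_size = 720, overlap = 80,
                         vignette = NULL, noise_sd = 0, seed = 1,
                         pitch = c(1.385, 1.339)) {
  if (overlap >= tile_size / 2) stop("overlap must be < tile_size / 2")
  if (!is.null(vignette) && any(vignette <= 0)) {
    stop("vignette must be strictly positive")
  }
  set.seed(seed)
  sz <- dim(image)
  starts_axis <- function(n) {
    if (n <= tile_size) return(0L)
    s <- seq(0L, n - tile_size, by = tile_size - overlap)
    unique(c(s, n - tile_size))
  }
  sx <- starts_axis(sz[1])
  sy <- starts_axis(sz[2])
  ts_x <- min(tile_size, sz[1])
  ts_y <- min(tile_size, sz[2])
  tiles <- list()
  offsets <- NULL
  for (oy in sy) for (ox in sx) {
    t_ <- image[(ox + 1):(ox + ts_x), (oy + 1):(oy + ts_y), drop = FALSE]
    if (!is.null(vignette)) t_ <- t_ * vignette[1:ts_x, 1:ts_y]
    if (noise_sd > 0) {
      t_ <- matrix(
        pmax(t_ * (1 + noise_sd * stats::rnorm(length(t_))), 0),
        nrow(t_), ncol(t_)
      )
    }
    tiles[[length(tiles) + 1L]] <- t_
    offsets <- rbind(offsets, c(ox * pitch[1], oy * pitch[2], 0))
  }
  structure(
    list(
      tiles = tiles, offsets = offsets, pitch = pitch,
      tile_size = c(ts_x, ts_y), overlap = overlap
    ),
    class = "tile_set"
  )
}

#' Single-tensor HARDI phantom
#'
#' Computes the closed-form diffusion signal `S = S0 * exp(-b n' D n)` per
#' voxel, direction and shell. Antipodal symmetry holds exactly.
#'
#' @param dim Length-3 grid dimensions.
#' @param directions n x 3 unit gradient directions.
#' @param bvals Length-n b-values in s/mm^2.
#' @param tensor Either a single 3 x 3 symmetric positive-definite tensor
#'   (mm^2/s) applied everywhere, or a function `(pts) -> list of tensors`.
#' @param S0 Non-diffusion-weighted signal level.
#' @param spacing Voxel spacing (micrometers).
#' @return A `hardi_image`: `signal` (4D array, space x direction),
#'   `directions`, `bvals`, `spacing`, `origin`.
#' @export
make_hardi_phantom <- function(dim = c(8, 8, 8), directions, bvals,
                               tensor, S0 = 100, spacing = 200) {
  directions <- normalize_rows(matrix(as.numeric(directions), ncol = 3L))
  nd <- nrow(directions)
  stopifnot(length(bvals) == nd)
  spacing <- rep_len(spacing, 3L)
  check_spd <- function(D) {
    if (max(abs(D - t(D))) > 1e-10 || any(eigen(D, symmetric = TRUE,
      only.values = TRUE
    )$values <= 0)) {
      stop("diffusion tensor must be symmetric positive definite")
    }
  }
  sig <- array(0, dim = c(dim, nd))
  if (is.function(tensor)) {
    co <- grid_coordinates(voxel_grid(array(0, dim), spacing))
    tlist <- tensor(co)
    for (v in seq_len(prod(dim))) check_spd(tlist[[v]])
    for (j in seq_len(nd)) {
      n <- directions[j, ]
      q <- vapply(tlist, function(D) as.numeric(n %*% D %*% n), numeric(1))
      sig[, , , j] <- array(S0 * exp(-bvals[j] * q), dim = dim)
    }
  } else {
    check_spd(tensor)
    for (j in seq_len(nd)) {
      n <- directions[j, ]
      q <- as.numeric(n %*% tensor %*% n)
      sig[, , , j] <- S0 * exp(-bvals[j] * q)
    }
  }
  structure(
    list(
      signal = sig, directions = directions, bvals = as.numeric(bvals),
      spacing = spacing, origin = c(0, 0, 0)
    ),
    class = "hardi_image"
  )
}

#' Synthetic tractogram with per-streamline voxel oracles
#'
#' Generates polylines with known geometry inside a bounding box; each
#' streamline's metadata records the 0-based indices of the reference-grid
#' voxels it traverses, serving as the oracle for selection and density
#' tests. Straight streamlines run axis-aligned along x through a voxel row,
#' so their oracle is that exact row.
#'
#' @param n Number of streamlines (`>= 0`).
#' @param geometry `"straight"`, `"arc"` or `"helix"`.
#' @param bbox 2 x 3 matrix: world min / max corners (micrometers).
#' @param grid Reference [voxel_grid] (data ignored) for the voxel oracles.
#' @param seed Integer RNG seed.
#' @return A [tractogram]; `metadata$voxels[[i]]` holds streamline i's
#'   oracle voxel index matrix.
#' @export
make_tractogram_phantom <- function(n, geometry = c("straight", "arc", "helix"),
                                    bbox, grid, seed = 1) {
  geometry <- match.arg(geometry)
  stopifnot(n >= 0)
  set.seed(seed)
  if (n == 0) return(tractogram(list(), metadata = list(voxels = list())))
  d3 <- dim(grid$data)[1:3]
  streamlines <- vector("list", n)
  voxels <- vector("list", n)
  for (i in seq_len(n)) {
    if (geometry == "straight") {
      jy <- sample.int(d3[2], 1L) - 1L
      kz <- sample.int(d3[3], 1L) - 1L
      y <- grid$origin[2] + jy * grid$spacing[2]
      z <- grid$origin[3] + kz * grid$spacing[3]
      xs <- seq(bbox[1, 1], bbox[2, 1], length.out = 50)
      s <- cbind(xs, y, z)
      ix <- 0:(d3[1] - 1L)
      xw <- grid$origin[1] + ix * grid$spacing[1]
      keep <- xw >= bbox[1, 1] - grid$spacing[1] / 2 &
        xw <= bbox[2, 1] + grid$spacing[1] / 2
      voxels[[i]] <- cbind(ix[keep], jy, kz)
    } else {
      ctr <- bbox[1, ] + stats::runif(3, 0.3, 0.7) * (bbox[2, ] - bbox[1, ])
      rad <- 0.2 * min(bbox[2, ] - bbox[1, ])
      th <- seq(0, if (geometry == "arc") pi else 4 * pi, length.out = 120)
      zlift <- if (geometry == "helix") {
        seq(0, 0.3 * (bbox[2, 3] - bbox[1, 3]), length.out = 120)
      } else {
        0
      }
      s <- cbind(
        ctr[1] + rad * cos(th), ctr[2] + rad * sin(th), ctr[3] + zlift
      )
      # oracle by dense resampling at a tenth of a voxel
      dense <- densify_polyline(s, min(grid$spacing) / 10)
      vi <- unique(round(world_to_voxel(grid, dense)))
      ok <- vi[, 1] >= 0 & vi[, 1] < d3[1] & vi[, 2] >= 0 & vi[, 2] < d3[2] &
        vi[, 3] >= 0 & vi[, 3] < d3[3]
      voxels[[i]] <- vi[ok, , drop = FALSE]
    }
    streamlines[[i]] <- s
  }
  tractogram(streamlines, metadata = list(voxels = voxels))
}

# resample a polyline so consecutive points are at most `step` apart
#' @noRd
densify_polyline <- function(s, step) {
  if (nrow(s) < 2L) return(s)
  seg <- diff(s)
  len <- sqrt(rowSums(seg^2))
  out <- vector("list", nrow(s) - 1L)
  for (i in seq_len(nrow(s) - 1L)) {
    k <- max(1L, ceiling(len[i] / step))
    tt <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    out[[i]] <- cbind(
      s[i, 1] + tt * seg[i, 1],
      s[i, 2] + tt * seg[i, 2],
      s[i, 3] + tt * seg[i, 3]
    )
  }
  rbind(do.call(rbind, out), s[nrow(s), , drop = FALSE])
}
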