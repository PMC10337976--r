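# The flatmap-stack coordinate system: a 3D image representation of the
# cortex whose in-plane axes index position on the (flat-mapped) cortical
# surface and whose third axis indexes relative cortical depth.
#
# Construction: surface normals are seeded on the inner (white-matter side)
# and outer (pial side) cortex boundaries, diffused through the cortical
# thickness by discrete heat propagation with renormalization, and
# integrated into trajectories from the inner to the outer boundary. A
# trajectory inherits the 2D flatmap coordinate of the mid-surface point it
# crosses; its relative arc length provides the depth coordinate.

#' Compute the through-cortex direction field by heat propagation
#'
#' The directional information seeded at the cortex boundaries (inner
#' boundary: normals pointing into the cortex; outer boundary: normals
#' pointing away from it) is diffused through the cortical thickness and
#' normalized. Two discretizations are provided:
#'
#' * `"potential"` (default): heat propagation of a scalar potential held
#'   at 0 on the inner and 1 on the outer boundary (red-black SOR
#'   relaxation of the discrete Laplace equation, free lateral borders);
#'   the field is the normalized potential gradient, lightly smoothed to
#'   suppress voxelization noise. At the boundaries the gradient of the
#'   equilibrium potential is exactly the surface normal direction, and the
#'   free-border condition makes the field run parallel to any lateral cut
#'   of the cortex mask, which keeps trajectories near flatmap patch
#'   borders on course.
#' * `"vector"`: literal componentwise diffusion of the boundary normal
#'   vectors (Jacobi averaging with the boundary values held fixed,
#'   renormalized each sweep). Boundary normals are estimated by local PCA
#'   plane fits on the one-voxel boundary sheets.
#'
#' @param cortex A [cortex_model].
#' @param tol Convergence tolerance: maximum per-sweep potential change
#'   (`"potential"`, default 1e-6) or maximum angular change in degrees
#'   (`"vector"`, default 0.02).
#' @param max_iter Maximum number of sweeps.
#' @param method `"potential"` or `"vector"`.
#' @param smooth_sigma Gaussian smoothing of the field in voxels
#'   (masked-normalized; 0 disables).
#' @return A `direction_field`: `field` (4D x,y,z-component array, zero
#'   outside the cortex), `domain` (logical array), `spacing`, `origin`.
#' @export
compute_direction_field <- function(cortex, tol = NULL, max_iter = 5000L,
                                    method = c("potential", "vector"),
                                    smooth_sigma = 1.5) {
  method <- match.arg(method)
  interior <- cortex$interior$data > 0
  inner <- cortex$inner_boundary$data > 0
  outer <- cortex$outer_boundary$data > 0
  d3 <- dim(interior)
  domain <- interior | inner | outer
  fixed <- inner | outer
  if (method == "potential") {
    if (is.null(tol)) tol <- 1e-6
    return(direction_field_potential(
      domain, inner, outer, tol, max_iter, smooth_sigma,
      cortex$interior$spacing, cortex$interior$origin
    ))
  }
  if (is.null(tol)) tol <- 0.02

  # boundary normals: local PCA plane fit on each boundary voxel sheet
  # (robust to stair-stepping and to the sheet ending at a patch edge),
  # oriented by the gradient of the smoothed domain indicator
  # (shift3 by +e places a[p - e] at p, hence the sign convention)
  sm <- gauss_smooth3(array(as.numeric(domain), d3), 1.5)
  gx <- (shift3(sm, c(-1L, 0L, 0L), 0) - shift3(sm, c(1L, 0L, 0L), 0)) / 2
  gy <- (shift3(sm, c(0L, -1L, 0L), 0) - shift3(sm, c(0L, 1L, 0L), 0)) / 2
  gz <- (shift3(sm, c(0L, 0L, -1L), 0) - shift3(sm, c(0L, 0L, 1L), 0)) / 2
  vx <- array(0, d3); vy <- array(0, d3); vz <- array(0, d3)
  set_seeds <- function(bmask, sign_) {
    nrm <- sheet_normals(bmask)
    idx <- which(bmask)
    gor <- cbind(gx[idx], gy[idx], gz[idx]) * sign_
    flip <- rowSums(nrm * gor) < 0
    nrm[flip, ] <- -nrm[flip, ]
    vx[idx] <<- nrm[, 1]; vy[idx] <<- nrm[, 2]; vz[idx] <<- nrm[, 3]
  }
  # inner: into the cortex (+gradient); outer: away from it (-gradient)
  set_seeds(inner, +1)
  set_seeds(outer, -1)
  nrm <- sqrt(vx^2 + vy^2 + vz^2)
  bad_seed <- fixed & nrm < 1e-12
  if (any(bad_seed)) stop("degenerate boundary normals on ", sum(bad_seed), " voxels")

  offs <- neighbor_offsets(6L)
  dom_num <- array(as.numeric(domain), d3)
  free <- domain & !fixed
  cos_tol <- cos(tol * pi / 180)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ax <- array(0, d3); ay <- array(0, d3); az <- array(0, d3)
    cnt <- array(0, d3)
    for (r in seq_len(nrow(offs))) {
      o <- offs[r, ]
      ax <- ax + shift3(vx, o, 0)
      ay <- ay + shift3(vy, o, 0)
      az <- az + shift3(vz, o, 0)
      cnt <- cnt + shift3(dom_num, o, 0)
    }
    nn <- sqrt(ax^2 + ay^2 + az^2)
    upd <- free & cnt > 0 & nn > 1e-12
    nxv <- vx; nyv <- vy; nzv <- vz
    nxv[upd] <- ax[upd] / nn[upd]
    nyv[upd] <- ay[upd] / nn[upd]
    nzv[upd] <- az[upd] / nn[upd]
    # angular change on voxels that already had a direction
    had <- free & (vx != 0 | vy != 0 | vz != 0)
    if (any(had)) {
      dp <- vx[had] * nxv[had] + vy[had] * nyv[had] + vz[had] * nzv[had]
      moved <- min(dp)
    } else {
      moved <- -1
    }
    vx <- nxv; vy <- nyv; vz <- nzv
    filled <- !any(free & !(vx != 0 | vy != 0 | vz != 0))
    if (filled && moved >= cos_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(sprintf(
      "direction field did not converge in %d sweeps (residual cos %.6f)",
      max_iter, moved
    ))
  }
  if (any(free & !(vx != 0 | vy != 0 | vz != 0))) {
    stop("interior voxels unreachable from the boundaries")
  }
  field <- array(0, dim = c(d3, 3L))
  field[, , , 1] <- vx; field[, , , 2] <- vy; field[, , , 3] <- vz
  field <- smooth_field4(field, domain, smooth_sigma)
  structure(
    list(
      field = field, domain = domain,
      spacing = cortex$interior$spacing, origin = cortex$interior$origin
    ),
    class = "direction_field"
  )
}

# masked-normalized Gaussian smoothing of a unit-vector field, followed by
# renormalization; zero outside the domain
#' @noRd
smooth_field4 <- function(field, domain, sigma) {
  if (sigma <= 0) return(field)
  d3 <- dim(field)[1:3]
  m <- array(as.numeric(domain), d3)
  sm_m <- pmax(gauss_smooth3(m, sigma), 1e-9)
  for (c_ in 1:3) {
    field[, , , c_] <- gauss_smooth3(field[, , , c_] * m, sigma) / sm_m
  }
  nn <- sqrt(field[, , , 1]^2 + field[, , , 2]^2 + field[, , , 3]^2)
  nn[nn == 0] <- 1
  for (c_ in 1:3) field[, , , c_] <- field[, , , c_] / nn * m
  field
}

# heat-equilibrium (discrete Laplace) depth potential: 0 on the inner and
# 1 on the outer boundary, free elsewhere; red-black SOR relaxation, then
# the field is the smoothed, normalized potential gradient
#' @noRd
direction_field_potential <- function(domain, inner, outer, tol, max_iter,
                                      smooth_sigma, spacing, origin) {
  d3 <- dim(domain)
  fixed <- inner | outer
  free <- domain & !fixed
  u <- array(0.5, d3)
  u[inner] <- 0
  u[outer] <- 1
  dom_num <- array(as.numeric(domain), d3)
  offs <- neighbor_offsets(6L)
  idx <- as.matrix(expand.grid(
    seq_len(d3[1]), seq_len(d3[2]), seq_len(d3[3])
  ))
  parity <- array((idx[, 1] + idx[, 2] + idx[, 3]) %% 2L == 0L, d3)
  colors <- list(free & parity, free & !parity)
  omega <- 2 / (1 + sin(pi / max(d3)))
  converged <- FALSE
  resid <- Inf
  for (it in seq_len(max_iter)) {
    resid <- 0
    for (col in colors) {
      acc <- array(0, d3)
      cnt <- array(0, d3)
      ud <- u * dom_num
      for (r in seq_len(nrow(offs))) {
        acc <- acc + shift3(ud, offs[r, ], 0)
        cnt <- cnt + shift3(dom_num, offs[r, ], 0)
      }
      upd <- col & cnt > 0
      new <- acc[upd] / cnt[upd]
      delta <- new - u[upd]
      u[upd] <- u[upd] + omega * delta
      resid <- max(resid, max(abs(delta)))
    }
    if (resid < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(sprintf(
      "depth potential did not converge in %d sweeps (residual %.3g)",
      max_iter, resid
    ))
  }
  # gradient within the domain: central where possible, one-sided at edges
  grad_axis <- function(ax) {
    e <- c(0L, 0L, 0L)
    e[ax] <- 1L
    up <- shift3(u, -e, 0) # u[p + e]
    dn <- shift3(u, e, 0) # u[p - e]
    upd <- shift3(dom_num, -e, 0) > 0
    dnd <- shift3(dom_num, e, 0) > 0
    g <- array(0, d3)
    both <- domain & upd & dnd
    g[both] <- (up[both] - dn[both]) / 2
    onlyu <- domain & upd & !dnd
    g[onlyu] <- up[onlyu] - u[onlyu]
    onlyd <- domain & !upd & dnd
    g[onlyd] <- u[onlyd] - dn[onlyd]
    g
  }
  field <- array(0, dim = c(d3, 3L))
  field[, , , 1] <- grad_axis(1) / spacing[1]
  field[, , , 2] <- grad_axis(2) / spacing[2]
  field[, , , 3] <- grad_axis(3) / spacing[3]
  nn <- sqrt(field[, , , 1]^2 + field[, , , 2]^2 + field[, , , 3]^2)
  if (any(free & nn == 0)) {
    stop("interior voxels unreachable from the boundaries")
  }
  nn[nn == 0] <- 1
  for (c_ in 1:3) field[, , , c_] <- field[, , , c_] / nn * dom_num
  field <- smooth_field4(field, domain, smooth_sigma)
  structure(
    list(field = field, domain = domain, spacing = spacing, origin = origin),
    class = "direction_field"
  )
}

# Per-voxel normals of a one-voxel-thick boundary sheet: PCA of the
# neighboring sheet voxels within a 2.5-voxel radius, the normal being the
# smallest-covariance eigenvector. Moments are accumulated with array
# shifts so the cost is linear in the grid size.
#' @noRd
sheet_normals <- function(bmask) {
  d3 <- dim(bmask)
  m <- array(as.numeric(bmask), d3)
  offs <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  offs <- offs[rowSums(offs^2) <= 2.5^2, , drop = FALSE]
  W <- array(0, d3)
  M1 <- list(array(0, d3), array(0, d3), array(0, d3))
  M2 <- matrix(list(), 3, 3)
  for (a in 1:3) for (b in a:3) M2[[a, b]] <- array(0, d3)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    sh <- shift3(m, o, 0)
    W <- W + sh
    for (a in 1:3) {
      if (o[a] != 0) M1[[a]] <- M1[[a]] + (-o[a]) * sh
    }
    for (a in 1:3) for (b in a:3) {
      if (o[a] != 0 && o[b] != 0) M2[[a, b]] <- M2[[a, b]] + o[a] * o[b] * sh
    }
  }
  idx <- which(bmask)
  n <- length(idx)
  out <- matrix(0, n, 3L)
  w <- W[idx]
  mu <- cbind(M1[[1]][idx], M1[[2]][idx], M1[[3]][idx]) / w
  cv <- array(0, dim = c(n, 3, 3))
  for (a in 1:3) for (b in a:3) {
    v <- M2[[a, b]][idx] / w - mu[, a] * mu[, b]
    cv[, a, b] <- v
    cv[, b, a] <- v
  }
  for (i in seq_len(n)) {
    ev <- eigen(cv[i, , ], symmetric = TRUE)
    out[i, ] <- ev$vectors[, 3]
  }
  out
}

# trilinear sample of the (normalized) direction field at world points
#' @noRd
field_at <- function(field, pts) {
  g <- voxel_grid(field$field, field$spacing, field$origin)
  v <- interp3(field$field, world_to_voxel(g, pts), mode = "linear", fill = 0)
  v <- matrix(v, ncol = 3L)
  normalize_rows(v)
}

# Batch fixed-step integration of the direction field from `starts` until
# each trajectory enters the outer boundary (success) or fails. Returns a
# list with `paths` (list of k x 3 matrices), `ok` flags and `lengths`.
#' @noRd
trace_batch <- function(starts, field, outer, step, max_len) {
  n <- nrow(starts)
  g <- voxel_grid(field$field, field$spacing, field$origin)
  d3 <- dim(field$domain)
  max_steps <- ceiling(max_len / step) + 1L
  pos <- starts
  active <- rep(TRUE, n)
  done_ok <- rep(FALSE, n)
  end_step <- rep(NA_integer_, n)
  hist <- vector("list", max_steps)
  hist[[1]] <- pos
  vox_state <- function(p) {
    vi <- round(world_to_voxel(g, p))
    inb <- vi[, 1] >= 0 & vi[, 1] < d3[1] & vi[, 2] >= 0 & vi[, 2] < d3[2] &
      vi[, 3] >= 0 & vi[, 3] < d3[3]
    lin <- 1 + pmax(0, vi[, 1]) + d3[1] * (pmax(0, vi[, 2]) + d3[2] * pmax(0, vi[, 3]))
    st <- rep("off", nrow(p))
    st[inb & outer[lin]] <- "outer"
    st[inb & field$domain[lin] & !outer[lin]] <- "in"
    st
  }
  st <- vox_state(pos)
  done_ok[active & st == "outer"] <- TRUE
  end_step[active & st != "in"] <- 1L
  active[st != "in"] <- FALSE
  for (k in 2:max_steps) {
    if (!any(active)) break
    v <- field_at(field, pos[active, , drop = FALSE])
    stalled <- rowSums(v^2) < 0.25
    pos[active, ] <- pos[active, , drop = FALSE] + step * v
    hist[[k]] <- pos
    st <- vox_state(pos[active, , drop = FALSE])
    idx <- which(active)
    hit <- st == "outer"
    off <- st == "off" | stalled
    done_ok[idx[hit]] <- TRUE
    end_step[idx[hit | off]] <- k
    active[idx[hit | off]] <- FALSE
  }
  end_step[is.na(end_step)] <- max_steps # ran out of length: failed
  done_ok[is.na(end_step)] <- FALSE
  paths <- vector("list", n)
  used <- min(max_steps, length(hist))
  stack <- array(NA_real_, dim = c(used, n, 3L))
  for (k in seq_len(used)) {
    if (!is.null(hist[[k]])) stack[k, , ] <- hist[[k]]
  }
  for (i in seq_len(n)) {
    ke <- min(end_step[i], used)
    paths[[i]] <- matrix(stack[seq_len(ke), i, ], ncol = 3L)
  }
  list(paths = paths, ok = done_ok, lengths = (end_step - 1L) * step)
}

#' Trace a single depth trajectory through the cortex
#'
#' Fixed-step integration of the trilinearly interpolated direction field
#' from an inner-boundary point until the outer boundary is crossed.
#'
#' @param start Length-3 world coordinate on the inner boundary.
#' @param field A `direction_field` from [compute_direction_field()].
#' @param cortex The [cortex_model] (supplies the outer boundary mask).
#' @param step Integration step in micrometers (at most half the voxel
#'   spacing).
#' @param max_len Abandon the trajectory beyond this arc length
#'   (micrometers); failed trajectories are flagged, not an error.
#' @return A `trajectory`: `points` (k x 3), `arclen` (cumulative, see
#'   micrometers), `ok` (reached the outer boundary).
#' @export
trace_trajectory <- function(start, field, cortex, step = NULL, max_len = NULL) {
  if (is.null(step)) step <- min(field$spacing) / 2
  if (step > min(field$spacing) / 2 + 1e-9) {
    stop("step must be at most half the voxel spacing")
  }
  if (is.null(max_len)) max_len <- 5 * estimate_thickness(cortex)
  tb <- trace_batch(
    matrix(start, ncol = 3L), field,
    cortex$outer_boundary$data > 0, step, max_len
  )
  p <- tb$paths[[1]]
  structure(
    list(points = p, arclen = (seq_len(nrow(p)) - 1L) * step, ok = tb$ok[1]),
    class = "trajectory"
  )
}

# crude cortical thickness estimate: interior volume / inner boundary area
#' @noRd
estimate_thickness <- function(cortex) {
  sp <- cortex$interior$spacing
  v <- mask_count(cortex$interior) * prod(sp)
  a <- mask_count(cortex$inner_boundary) * sp[1] * sp[2]
  max(v / max(a, 1), 4 * min(sp))
}

#' Build a flatmap stack from a cortex model and direction field
#'
#' Traces trajectories from the inner-boundary voxels (optionally
#' supersampled within each seed voxel for a denser bundle), assigns each
#' trajectory the flatmap (u,v) of its mid-surface crossing (the vertex's
#' own coordinate when the trajectory passes within one voxel of a mesh
#' vertex, barycentric interpolation on the crossed triangle otherwise), and
#' gives every trajectory sample the coordinate (u, v, relative arc-length
#' depth). The dense stack-to-world map is built by kernel-weighted
#' scattered interpolation of the trajectory samples per depth layer, and
#' the world-to-stack map by rasterizing the samples into cortex voxels
#' (averaging where several land) with a hole-filling relaxation.
#'
#' @param cortex A [cortex_model].
#' @param field A `direction_field`.
#' @param dims Stack dimensions `c(U, V, D)`; the default 500 x 500 x 50
#'   gives 50 equidistant depth layers.
#' @param step Trajectory integration step (micrometers).
#' @param seed_supersample Seeds per axis within each inner-boundary voxel.
#' @param max_fail Maximum tolerated fraction of failed trajectories.
#' @param uv_smooth Masked Gaussian smoothing (voxels) applied to the
#'   in-plane channels of the world-to-stack map (0 disables).
#' @return A `flatmap_stack`: `dims`, `to_world` (U x V x D x 3 world
#'   coordinates, `NA` where the stack is outside the mapped cortex),
#'   `from_world` ([voxel_grid], 4D with channels u,v,depth in `[0,1]`,
#'   `NA` outside the cortex), `provenance`.
#' @export
build_flatstack <- function(cortex, field, dims = c(500L, 500L, 50L),
                            step = NULL, seed_supersample = 2L,
                            max_fail = 0.2, uv_smooth = 1) {
  sp <- cortex$interior$spacing
  if (is.null(step)) step <- min(sp) / 2
  mesh <- cortex$mid_surface
  if (is.null(mesh$flat_uv) || nrow(mesh$flat_uv) == 0) {
    stop("cortex mesh lacks flat_uv coordinates")
  }
  g <- cortex$interior
  d3 <- dim(g$data)[1:3]

  # seeds: all inner-boundary voxel centers, supersampled within the voxel
  seed_vox <- which(cortex$inner_boundary$data > 0, arr.ind = TRUE) - 1L
  base <- voxel_to_world(g, seed_vox)
  s <- max(1L, as.integer(seed_supersample))
  if (s > 1L) {
    off1 <- (seq_len(s) - (s + 1) / 2) / s
    og <- as.matrix(expand.grid(off1, off1, off1))
    starts <- do.call(rbind, lapply(seq_len(nrow(og)), function(i) {
      sweep(base, 2, og[i, ] * sp, "+")
    }))
  } else {
    starts <- base
  }
  # keep only seeds whose containing voxel is in the traced domain
  sv <- round(world_to_voxel(g, starts))
  inb <- sv[, 1] >= 0 & sv[, 1] < d3[1] & sv[, 2] >= 0 & sv[, 2] < d3[2] &
    sv[, 3] >= 0 & sv[, 3] < d3[3]
  lin_s <- 1 + pmax(0, sv[, 1]) + d3[1] * (pmax(0, sv[, 2]) + d3[2] * pmax(0, sv[, 3]))
  starts <- starts[inb & field$domain[lin_s], , drop = FALSE]

  max_len <- 5 * estimate_thickness(cortex)
  tb <- trace_batch(starts, field, cortex$outer_boundary$data > 0, step, max_len)
  ok <- tb$ok & tb$lengths > 2 * step
  uv <- assign_trajectory_uv(tb$paths, ok, mesh, min(sp))
  ok <- ok & !is.na(uv[, 1])
  fail_frac <- 1 - mean(ok)
  if (fail_frac > max_fail) {
    stop(sprintf(
      "%.1f%% of trajectories failed (tracing or mesh crossing); limit %.0f%%",
      100 * fail_frac, 100 * max_fail
    ))
  }

  U <- dims[1]; V <- dims[2]; D <- dims[3]

  # ---- from_world: average (u, v, depth) of samples per cortex voxel ----
  keep <- which(ok)
  npts <- vapply(tb$paths[keep], nrow, integer(1))
  allp <- do.call(rbind, tb$paths[keep])
  traj_id <- rep(seq_along(keep), npts)
  arc <- unlist(lapply(npts, function(k) seq_len(k) - 1L)) * step
  tot <- (npts - 1L) * step
  # trajectory endpoints sit at boundary voxel centers, on average half a
  # voxel inside the physical surfaces; extend the arc-length span by half
  # a voxel on each side so depth 0/1 refer to the surfaces themselves
  h <- min(sp) / 2
  depth <- (arc + h) / (tot[traj_id] + 2 * h)
  su <- uv[keep, 1][traj_id]
  sv <- uv[keep, 2][traj_id]

  vi <- round(world_to_voxel(g, allp))
  inb <- vi[, 1] >= 0 & vi[, 1] < d3[1] & vi[, 2] >= 0 & vi[, 2] < d3[2] &
    vi[, 3] >= 0 & vi[, 3] < d3[3]
  lin <- 1 + vi[inb, 1] + d3[1] * (vi[inb, 2] + d3[2] * vi[inb, 3])
  acc <- rowsum(cbind(su[inb], sv[inb], depth[inb], 1), group = lin)
  glin <- as.integer(rownames(acc))
  fw <- array(NA_real_, dim = c(d3, 3L))
  nvox <- prod(d3)
  fw[glin] <- acc[, 1] / acc[, 4]
  fw[glin + nvox] <- acc[, 2] / acc[, 4]
  fw[glin + 2 * nvox] <- acc[, 3] / acc[, 4]
  domain <- field$domain
  fw <- fill_holes4(fw, domain, max_sweeps = 60L)
  # de-noise the in-plane channels (u, v are constant along trajectories and
  # smooth across them, so a small masked smoothing removes per-trajectory
  # jitter without biasing the depth channel, which is left untouched)
  if (uv_smooth > 0) {
    def <- !is.na(fw[, , , 1])
    m <- array(as.numeric(def), d3)
    smm <- pmax(gauss_smooth3(m, uv_smooth), 1e-9)
    for (c_ in 1:2) {
      ch <- fw[, , , c_]
      ch[!def] <- 0
      ch <- gauss_smooth3(ch, uv_smooth) / smm
      ch[!def] <- NA_real_
      fw[, , , c_] <- ch
    }
  }
  from_world <- voxel_grid(fw, sp, g$origin)

  # ---- to_world: per-layer kernel scattered interpolation ----
  to_world <- array(NA_real_, dim = c(U, V, D, 3L))
  sigma_px <- max(1.2, 0.8 * sqrt(U * V / max(sum(ok), 1)))
  kx <- gauss_band(U, sigma_px)
  ky <- gauss_band(V, sigma_px)
  ui <- pmin(U, pmax(1L, round(uv[keep, 1] * (U - 1)) + 1L))
  vj <- pmin(V, pmax(1L, round(uv[keep, 2] * (V - 1)) + 1L))
  lin_uv <- ui + U * (vj - 1L)
  offs0 <- cumsum(c(0L, npts[-length(npts)]))
  for (dz in seq_len(D)) {
    dtarget <- (dz - 1) / (D - 1)
    # world position of each trajectory at this relative arc length
    # (same half-voxel end-extension as the depth parameterization)
    pos_d <- sample_paths_at(
      allp, offs0, npts,
      pmin(1, pmax(0, (dtarget * (tot + 2 * h) - h) / pmax(tot, 1e-9))),
      step, tot
    )
    num_x <- matrix(0, U, V); num_y <- matrix(0, U, V)
    num_z <- matrix(0, U, V); den <- matrix(0, U, V)
    sx <- rowsum(cbind(pos_d, 1), group = lin_uv)
    sl <- as.integer(rownames(sx))
    num_x[sl] <- sx[, 1]; num_y[sl] <- sx[, 2]; num_z[sl] <- sx[, 3]
    den[sl] <- sx[, 4]
    num_x <- kx %*% num_x %*% ky; num_y <- kx %*% num_y %*% ky
    num_z <- kx %*% num_z %*% ky; den <- kx %*% den %*% ky
    valid <- den > 1e-10
    lx <- matrix(NA_real_, U, V); ly <- matrix(NA_real_, U, V); lz <- matrix(NA_real_, U, V)
    lx[valid] <- num_x[valid] / den[valid]
    ly[valid] <- num_y[valid] / den[valid]
    lz[valid] <- num_z[valid] / den[valid]
    to_world[, , dz, 1] <- lx
    to_world[, , dz, 2] <- ly
    to_world[, , dz, 3] <- lz
  }

  structure(
    list(
      dims = c(U, V, D), to_world = to_world, from_world = from_world,
      provenance = list(
        step = step, seed_supersample = s, n_seeds = nrow(starts),
        n_failed = sum(!ok), fail_frac = fail_frac, sigma_px = sigma_px,
        cortex_dims = d3, spacing = sp, origin = g$origin
      )
    ),
    class = "flatmap_stack"
  )
}

#' @export
print.flatmap_stack <- function(x, ...) {
  cat(sprintf(
    "<flatmap_stack> %s; %d/%d trajectories failed\n",
    paste(x$dims, collapse = "x"),
    x$provenance$n_failed, x$provenance$n_seeds
  ))
  invisible(x)
}

# truncated-Gaussian banded convolution matrix (rows normalized later by
# the shared denominator field, so no normalization needed here)
#' @noRd
gauss_band <- function(n, sigma) {
  r <- ceiling(3 * sigma)
  i <- seq_len(n)
  K <- outer(i, i, function(a, b) {
    d <- a - b
    ifelse(abs(d) <= r, exp(-d^2 / (2 * sigma^2)), 0)
  })
  K
}

# world position of each trajectory at relative arc length `dtarget`;
# `allp` stacks all kept paths, `offs0[i]` is the row offset of path i
#' @noRd
sample_paths_at <- function(allp, offs0, npts, dtarget, step, tot) {
  kf <- dtarget * tot / step # fractional sample index (0-based)
  k0 <- pmin(npts - 1L, pmax(0L, floor(kf)))
  k1 <- pmin(npts - 1L, k0 + 1L)
  fr <- pmin(1, pmax(0, kf - k0))
  r0 <- offs0 + k0 + 1L
  r1 <- offs0 + k1 + 1L
  (1 - fr) * allp[r0, , drop = FALSE] + fr * allp[r1, , drop = FALSE]
}

# assign flatmap (u,v) to each trajectory from its mid-surface crossing
#' @noRd
assign_trajectory_uv <- function(paths, ok, mesh, voxel) {
  n <- length(paths)
  uv <- matrix(NA_real_, n, 2L)
  verts <- mesh$vertices
  # occupancy of mesh vertices on a coarse lattice to prefilter samples
  cell <- 2 * voxel
  vcell <- floor(sweep(verts, 2, apply(verts, 2, min), "-") / cell)
  vkey <- paste(vcell[, 1], vcell[, 2], vcell[, 3])
  vmin <- apply(verts, 2, min)
  keyset <- unique(vkey)
  # incident triangles per vertex
  tri <- mesh$triangles
  inc <- vector("list", nrow(verts))
  if (nrow(tri) > 0) {
    for (c_ in 1:3) {
      for (r in seq_len(nrow(tri))) {
        v <- tri[r, c_]
        inc[[v]] <- c(inc[[v]], r)
      }
    }
  }
  id_list <- list()
  pt_list <- list()
  for (i in which(ok)) {
    p <- paths[[i]]
    pc <- floor(sweep(p, 2, vmin, "-") / cell)
    near <- paste(pc[, 1], pc[, 2], pc[, 3]) %in% keyset
    if (!any(near)) {
      # fall back to every sample (mesh cells may just straddle lattice cells)
      near <- rep(TRUE, nrow(p))
    }
    sel <- which(near)
    id_list[[length(id_list) + 1L]] <- rep(i, length(sel))
    pt_list[[length(pt_list) + 1L]] <- p[sel, , drop = FALSE]
  }
  if (length(id_list) == 0) return(uv)
  cand_id <- unlist(id_list)
  cand_pt <- do.call(rbind, pt_list)
  # chunked nearest-vertex search
  nnv <- integer(length(cand_id))
  nnd <- numeric(length(cand_id))
  v2 <- rowSums(verts^2)
  chunk <- 4000L
  for (s0 in seq(1L, length(cand_id), by = chunk)) {
    s1 <- min(length(cand_id), s0 + chunk - 1L)
    P <- cand_pt[s0:s1, , drop = FALSE]
    d2 <- outer(rowSums(P^2), v2, "+") - 2 * P %*% t(verts)
    j <- max.col(-d2, ties.method = "first")
    nnv[s0:s1] <- j
    nnd[s0:s1] <- sqrt(pmax(0, d2[cbind(seq_len(nrow(P)), j)]))
  }
  by_traj <- split(seq_along(cand_id), cand_id)
  for (nm in names(by_traj)) {
    i <- as.integer(nm)
    rows <- by_traj[[nm]]
    b <- rows[which.min(nnd[rows])]
    w <- nnv[b]
    p <- cand_pt[b, ]
    if (nnd[b] <= voxel) {
      # within one voxel of a mesh vertex: inherit its flatmap coordinate,
      # refined barycentrically when an incident triangle contains the point
      bres <- barycentric_uv(p, w, inc, mesh)
      uv[i, ] <- if (is.null(bres)) mesh$flat_uv[w, ] else bres
    } else if (nnd[b] <= 4 * voxel) {
      bres <- barycentric_uv(p, w, inc, mesh)
      uv[i, ] <- if (is.null(bres)) mesh$flat_uv[w, ] else bres
    } # else: no mesh crossing -> NA (trajectory excluded)
  }
  uv
}

# barycentric flatmap coordinate of point p on a triangle incident to
# vertex w; NULL if no incident triangle contains the projection
#' @noRd
barycentric_uv <- function(p, w, inc, mesh) {
  tris <- inc[[w]]
  if (length(tris) == 0) return(NULL)
  best <- NULL
  best_slack <- Inf
  for (t_ in tris) {
    v <- mesh$triangles[t_, ]
    A <- mesh$vertices[v[1], ]; B <- mesh$vertices[v[2], ]; C <- mesh$vertices[v[3], ]
    e1 <- B - A; e2 <- C - A; q <- p - A
    M <- rbind(c(sum(e1 * e1), sum(e1 * e2)), c(sum(e1 * e2), sum(e2 * e2)))
    rhs <- c(sum(q * e1), sum(q * e2))
    if (abs(det(M)) < 1e-12) next
    ab <- solve(M, rhs)
    bc <- c(1 - ab[1] - ab[2], ab[1], ab[2])
    slack <- -min(bc)
    if (slack < best_slack) {
      best_slack <- slack
      best <- bc[1] * mesh$flat_uv[v[1], ] + bc[2] * mesh$flat_uv[v[2], ] +
        bc[3] * mesh$flat_uv[v[3], ]
    }
  }
  if (is.null(best) || best_slack > 0.25) return(NULL)
  best
}

# relax undefined voxels of a 4D (3-channel) field toward the mean of their
# defined 6-neighbors, restricted to `domain`
#' @noRd
fill_holes4 <- function(fw, domain, max_sweeps = 60L) {
  d3 <- dim(fw)[1:3]
  offs <- neighbor_offsets(6L)
  for (sw in seq_len(max_sweeps)) {
    def <- !is.na(fw[, , , 1])
    holes <- domain & !def
    if (!any(holes)) break
    accs <- vector("list", 3L)
    for (c_ in 1:3) accs[[c_]] <- array(0, d3)
    cnt <- array(0, d3)
    defn <- array(as.numeric(def), d3)
    for (r in seq_len(nrow(offs))) {
      o <- offs[r, ]
      cnt <- cnt + shift3(defn, o, 0)
      for (c_ in 1:3) {
        ch <- fw[, , , c_]
        ch[!def] <- 0
        accs[[c_]] <- accs[[c_]] + shift3(ch, o, 0)
      }
    }
    fillable <- holes & cnt > 0
    if (!any(fillable)) break
    for (c_ in 1:3) {
      ch <- fw[, , , c_]
      ch[fillable] <- accs[[c_]][fillable] / cnt[fillable]
      fw[, , , c_] <- ch
    }
  }
  fw
}

#' Map a cortex volume into flatmap-stack space
#'
#' @param volume A [voxel_grid] on the cortex grid.
#' @param fs A `flatmap_stack`.
#' @param mode `"linear"` or `"nearest"` (use `"nearest"` for labels).
#' @param fill Value assigned outside the mapped cortex.
#' @return A stack-shaped [voxel_grid] (unit spacing, stack voxel units).
#' @export
map_to_stack <- function(volume, fs, mode = c("linear", "nearest"), fill = 0) {
  mode <- match.arg(mode)
  cm <- voxel_grid(fs$to_world, c(1, 1, 1), c(0, 0, 0))
  resample_with_map(volume, cm, mode = mode, fill = fill, label = (mode == "nearest"))
}

#' Map stack-space points back into world coordinates
#'
#' @param points n x 3 matrix of 0-based stack voxel coordinates.
#' @param fs A `flatmap_stack`.
#' @return A [point_set] of world points (trilinear lookup of the
#'   stack-to-world map).
#' @export
map_points_from_stack <- function(points, fs) {
  points <- matrix(as.numeric(points), ncol = 3L)
  d <- fs$dims
  if (any(points < -0.5) || any(sweep(points, 2, d - 0.5, ">"))) {
    stop("stack points out of bounds")
  }
  w <- interp3(fs$to_world, points, mode = "linear", fill = NA_real_)
  point_set(matrix(w, ncol = 3L))
}

#' Stack coordinates of world points
#'
#' Looks up the world-to-stack map; points outside the mapped cortex give
#' `NA` rows.
#'
#' @param fs A `flatmap_stack`.
#' @param pts n x 3 world coordinates (micrometers).
#' @return n x 3 matrix of continuous 0-based stack voxel coordinates.
#' @export
stack_coords_of_world <- function(fs, pts) {
  fwg <- fs$from_world
  v <- interp3(fwg$data, world_to_voxel(fwg, pts), mode = "linear", fill = NA_real_)
  v <- matrix(v, ncol = 3L)
  # fall back to nearest for points whose trilinear support touches a hole
  miss <- is.na(v[, 1])
  if (any(miss)) {
    vn <- interp3(fwg$data, world_to_voxel(fwg, pts[miss, , drop = FALSE]),
      mode = "nearest", fill = NA_real_
    )
    v[miss, ] <- matrix(vn, ncol = 3L)
  }
  cbind(
    v[, 1] * (fs$dims[1] - 1), v[, 2] * (fs$dims[2] - 1),
    v[, 3] * (fs$dims[3] - 1)
  )
}

#' Relative cortical depth of world points
#'
#' @param fs A `flatmap_stack`.
#' @return A function mapping an n x 3 world point matrix to depths in
#'   `[0, 1]` (`NA` outside the cortex), suitable for [classify_laminar()].
#' @export
stack_depth_fn <- function(fs) {
  function(pts) {
    sc <- stack_coords_of_world(fs, pts)
    sc[, 3] / (fs$dims[3] - 1)
  }
}

#' Project a stack over its depth axis
#'
#' @param stack A stack-shaped [voxel_grid] or 3D array.
#' @param reducer `"max"`, `"mean"` or `"sum"`.
#' @return 2D matrix (the flat projection).
#' @export
flat_projection <- function(stack, reducer = c("max", "mean", "sum")) {
  reducer <- match.arg(reducer)
  a <- if (inherits(stack, "voxel_grid")) stack$data else stack
  f <- switch(reducer,
    max = function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE),
    mean = function(x) mean(x, na.rm = TRUE),
    sum = function(x) sum(x, na.rm = TRUE)
  )
  apply(a, c(1, 2), f)
}

#' Validate flatmap-stack isotropy with back-projected spheres
#'
#' Places seed points equidistantly in the requested stack layers, maps them
#' to world space, samples an isotropic sphere surface around each, maps the
#' samples back into stack coordinates, and summarizes the resulting
#' ellipsoid by the eigenvalues of the sample covariance. The isotropy
#' score is `sqrt(lambda3 / lambda1)`, 1 for a perfectly isotropic mapping.
#'
#' @param fs A `flatmap_stack`.
#' @param layers 0-based stack depth layers to validate (default 5, 25, 45).
#' @param seed_spacing Seed grid spacing in stack voxels.
#' @param radius Sphere radius in micrometers.
#' @param n_sphere_samples Sphere-surface samples per seed.
#' @param seed Integer RNG seed (controls the random rotation applied to the
#'   deterministic sphere sample).
#' @return An `isotropy_report`: `seeds` data frame (u, v, layer,
#'   eigenvalues, score), `per_layer` histograms, `n_skipped`.
#' @export
isotropy_validate <- function(fs, layers = c(5L, 25L, 45L), seed_spacing = 25L,
                              radius = 100, n_sphere_samples = 200, seed = 1) {
  stopifnot(all(layers >= 0), all(layers < fs$dims[3]))
  set.seed(seed)
  sph <- fibonacci_sphere(n_sphere_samples) %*% t(random_rotation()) * radius
  rows <- list()
  n_skipped <- 0L
  for (L in layers) {
    us <- seq(1L, fs$dims[1], by = seed_spacing)
    vs <- seq(1L, fs$dims[2], by = seed_spacing)
    for (u in us) for (v in vs) {
      w <- fs$to_world[u, v, L + 1L, ]
      if (any(is.na(w))) next
      pts <- sweep(sph, 2, w, "+")
      sc <- stack_coords_of_world(fs, pts)
      if (any(is.na(sc))) {
        n_skipped <- n_skipped + 1L
        next
      }
      ev <- eigen(stats::cov(sc), symmetric = TRUE, only.values = TRUE)$values
      ev <- pmax(ev, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        u = u - 1L, v = v - 1L, layer = L,
        lambda1 = ev[1], lambda2 = ev[2], lambda3 = ev[3],
        score = sqrt(ev[3] / max(ev[1], 1e-300))
      )
    }
  }
  seeds <- if (length(rows)) do.call(rbind, rows) else
    data.frame(u = integer(0), v = integer(0), layer = integer(0),
      lambda1 = numeric(0), lambda2 = numeric(0), lambda3 = numeric(0),
      score = numeric(0))
  per_layer <- lapply(split(seeds$score, seeds$layer), function(s) {
    graphics::hist(s, breaks = seq(0, 1, by = 0.05), plot = FALSE)
  })
  structure(
    list(seeds = seeds, per_layer = per_layer, n_skipped = n_skipped),
    class = "isotropy_report"
  )
}

#' @export
print.isotropy_report <- function(x, ...) {
  cat(sprintf(
    "<isotropy_report> %d seeds (%d skipped); median score %.3f\n",
    nrow(x$seeds), x$n_skipped, stats::median(x$seeds$score)
  ))
  invisible(x)
}
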