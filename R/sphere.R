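# Symmetric spherical direction design and HARDI utilities.
#
# An averaged diffusion template built in a left-right symmetric brain space
# must use a gradient scheme with two closures: antipodal equivalence
# S(x, n) = S(x, -n), and x-mirror symmetry
# S(x,y,z, nx,ny,nz) = S(-x,y,z, -nx,ny,nz). Directions are designed by
# electrostatic repulsion (charged particles on the sphere) over the fully
# symmetrized point set, with both closures enforced by construction.

# mirror across the x = 0 plane in direction space
#' @noRd
mirror_dir <- function(d) {
  d <- matrix(d, ncol = 3L)
  d[, 1] <- -d[, 1]
  d
}

#' Coulomb energy of a direction set
#'
#' Expands each representative to the antipodal pair and sums `1/distance`
#' over all point pairs. This is the objective the direction optimizer
#' minimizes, exposed for baseline comparisons.
#'
#' @param directions n x 3 unit vectors (one per antipodal pair).
#' @return Scalar energy.
#' @export
direction_energy <- function(directions) {
  P <- rbind(matrix(directions, ncol = 3L), -matrix(directions, ncol = 3L))
  dmat <- as.matrix(stats::dist(P))
  sum(1 / dmat[upper.tri(dmat)])
}

# energy and per-point gradient for the 2n-point antipodal expansion
#' @noRd
coulomb_eg <- function(reps) {
  n <- nrow(reps)
  P <- rbind(reps, -reps)
  m <- 2L * n
  dx <- outer(P[, 1], P[, 1], "-")
  dy <- outer(P[, 2], P[, 2], "-")
  dz <- outer(P[, 3], P[, 3], "-")
  d2 <- dx^2 + dy^2 + dz^2
  diag(d2) <- Inf
  d <- sqrt(d2)
  E <- sum(1 / d[upper.tri(d)])
  inv3 <- 1 / (d * d2)
  gx <- -rowSums(dx * inv3)
  gy <- -rowSums(dy * inv3)
  gz <- -rowSums(dz * inv3)
  G <- cbind(gx, gy, gz)
  # gradient w.r.t. the representatives (chain rule through the antipode)
  list(E = E, G = G[seq_len(n), , drop = FALSE] - G[n + seq_len(n), , drop = FALSE])
}

# assemble representatives from the parameterization:
# free pairs {x, mirror(x)}, on-plane classes (x = 0), optional x-axis class
#' @noRd
assemble_reps <- function(free, theta, has_ex) {
  parts <- list()
  if (nrow(free) > 0) parts <- c(parts, list(free, mirror_dir(free)))
  if (length(theta) > 0) {
    parts <- c(parts, list(cbind(0, cos(theta), sin(theta))))
  }
  if (has_ex) parts <- c(parts, list(matrix(c(1, 0, 0), 1)))
  do.call(rbind, parts)
}

#' @noRd
optimize_split <- function(n_free, n_plane, has_ex, max_iter, tol, lr0) {
  free <- normalize_rows(matrix(stats::rnorm(3 * n_free), ncol = 3L))
  if (n_free > 0) free[, 1] <- abs(free[, 1]) + 0.05 # keep off the mirror plane
  free <- normalize_rows(free)
  theta <- stats::runif(n_plane, 0, 2 * pi)
  lr <- lr0
  reps <- assemble_reps(free, theta, has_ex)
  eg <- coulomb_eg(reps)
  trace <- eg$E
  it <- 0L
  gnorm <- NA_real_
  for (it in seq_len(max_iter)) {
    n_f <- nrow(free)
    # pull the representative gradients back onto the parameters
    if (n_f > 0) {
      g_free <- eg$G[seq_len(n_f), , drop = FALSE] +
        mirror_dir(eg$G[n_f + seq_len(n_f), , drop = FALSE])
      # tangent projection on the sphere
      g_free <- g_free - free * rowSums(g_free * free)
    }
    if (length(theta) > 0) {
      gp <- eg$G[2 * n_f + seq_along(theta), , drop = FALSE]
      g_theta <- -gp[, 2] * sin(theta) + gp[, 3] * cos(theta)
    }
    gnorm <- sqrt(
      (if (n_f > 0) sum(g_free^2) else 0) +
        (if (length(theta) > 0) sum(g_theta^2) else 0)
    )
    if (gnorm < 1e-10) break
    accepted <- FALSE
    for (bt in 1:30) {
      free2 <- free
      theta2 <- theta
      if (n_f > 0) free2 <- normalize_rows(free - lr * g_free)
      if (length(theta) > 0) theta2 <- theta - lr * g_theta
      reps2 <- assemble_reps(free2, theta2, has_ex)
      eg2 <- coulomb_eg(reps2)
      if (eg2$E <= eg$E) {
        accepted <- TRUE
        break
      }
      lr <- lr / 2
    }
    if (!accepted) break
    dE <- eg$E - eg2$E
    free <- free2
    theta <- theta2
    eg <- eg2
    trace <- c(trace, eg$E)
    lr <- min(lr * 1.2, 1)
    if (dE < tol * max(abs(eg$E), 1)) break
  }
  list(
    reps = assemble_reps(free, theta, has_ex), E = eg$E, trace = trace,
    grad_norm = gnorm, iters = it
  )
}

#' Optimize a mirror- and antipodally-symmetric direction set
#'
#' Places charged particles on the sphere and relaxes them to an
#' electrostatic equilibrium (projected gradient descent on the Coulomb
#' `1/distance` energy of the antipodally expanded point set), with the two
#' required closures enforced by construction: representatives come in
#' x-mirror pairs, plus self-symmetric classes on the mirror plane or along
#' the x axis. For small n (<= 6) every split between paired and
#' self-symmetric classes is optimized and the best kept, which lets n = 3
#' reach the orthogonal (octahedral) optimum; larger n uses n/2 mirror
#' pairs (plus one on-plane class when n is odd).
#'
#' @param n Number of direction representatives (one per antipodal pair).
#' @param seed Integer RNG seed.
#' @param lr Initial gradient step size.
#' @param tol Relative energy-decrease convergence tolerance.
#' @param max_iter Maximum accepted iterations per restart.
#' @param restarts Random restarts per split.
#' @return A `direction_set`: `directions` (n x 3 unit vectors),
#'   `mirror_symmetric = TRUE`, `energy`, `energy_trace` (non-increasing),
#'   `provenance`.
#' @export
optimize_symmetric_directions <- function(n, seed = 0, lr = 0.05, tol = 1e-10,
                                          max_iter = 2000L, restarts = 3L) {
  stopifnot(n >= 1)
  set.seed(seed)
  splits <- if (n <= 6L) {
    out <- list()
    for (e in 0:min(1L, n)) {
      for (f in 0:((n - e) %/% 2L)) {
        out[[length(out) + 1L]] <- c(f, n - e - 2L * f, e)
      }
    }
    out
  } else {
    list(c(n %/% 2L, n %% 2L, 0L))
  }
  best <- NULL
  for (sp in splits) {
    for (r in seq_len(restarts)) {
      res <- optimize_split(sp[1], sp[2], sp[3] > 0, max_iter, tol, lr)
      res$split <- sp
      if (is.null(best) || res$E < best$E) best <- res
    }
  }
  dirs <- best$reps
  # closure sanity: every mirrored representative must be in the set
  # (up to antipodal equivalence), which holds by construction
  md <- mirror_dir(dirs)
  match_ang <- apply(abs(md %*% t(dirs)), 1, max)
  if (any(match_ang < 1 - 1e-9)) stop("mirror closure violated")
  structure(
    list(
      directions = dirs, mirror_symmetric = TRUE, energy = best$E,
      energy_trace = best$trace,
      provenance = list(
        n = n, seed = seed, split = best$split, lr = lr, tol = tol,
        iterations = best$iters, grad_norm = best$grad_norm
      )
    ),
    class = "direction_set"
  )
}

#' @export
print.direction_set <- function(x, ...) {
  cat(sprintf(
    "<direction_set> %d representatives, mirror_symmetric=%s, energy %.4f\n",
    nrow(x$directions), x$mirror_symmetric, x$energy
  ))
  invisible(x)
}

#' Minimum pairwise angle of a direction set
#'
#' Computed over the antipodally expanded set (so the angle between a
#' direction and another's antipode counts).
#'
#' @param directions n x 3 unit vectors.
#' @return Minimum angle in degrees.
#' @export
min_pairwise_angle <- function(directions) {
  d <- normalize_rows(matrix(directions, ncol = 3L))
  ca <- abs(d %*% t(d))
  diag(ca) <- 0
  acos(pmin(1, max(ca))) * 180 / pi
}

#' Interpolate a HARDI image onto new gradient directions
#'
#' Per voxel and shell, the signal at a new direction is an
#' inverse-angular-distance weighted combination of the k nearest source
#' directions, using the antipodally symmetrized angle
#' `min(ang(a,b), ang(a,-b))`. Weights are normalized (constant signals are
#' reproduced exactly); a new direction coinciding with a source copies it.
#'
#' @param img A `hardi_image`.
#' @param new_dirs n x 3 unit vectors or a `direction_set`.
#' @param k Number of nearest source directions.
#' @param power Inverse-distance exponent (weights `1 / angle^power`).
#' @param max_gap Error if a new direction is farther than this angle
#'   (radians) from every source in its shell.
#' @return A `hardi_image` on the new directions (replicated per b-shell).
#' @export
spherical_interpolate <- function(img, new_dirs, k = 8L, power = 2,
                                  max_gap = 0.5) {
  nd <- if (inherits(new_dirs, "direction_set")) new_dirs$directions else new_dirs
  nd <- normalize_rows(matrix(nd, ncol = 3L))
  shells <- unique(img$bvals)
  d3 <- dim(img$signal)[1:3]
  nvox <- prod(d3)
  sig <- matrix(img$signal, nrow = nvox)
  out_cols <- list()
  out_dirs <- list()
  out_bvals <- numeric(0)
  for (b in shells) {
    src <- which(img$bvals == b)
    sd_ <- img$directions[src, , drop = FALSE]
    ang <- acos(pmin(abs(nd %*% t(sd_)), 1)) # antipodally symmetrized
    W <- matrix(0, nrow(nd), length(src))
    for (i in seq_len(nrow(nd))) {
      a <- ang[i, ]
      if (min(a) > max_gap) {
        stop(sprintf(
          "new direction %d is %.1f deg from the nearest source (shell b=%g)",
          i, min(a) * 180 / pi, b
        ))
      }
      if (min(a) < 1e-9) {
        W[i, which.min(a)] <- 1
        next
      }
      ks <- order(a)[seq_len(min(k, length(a)))]
      w <- 1 / a[ks]^power
      W[i, ks] <- w / sum(w)
    }
    out_cols[[length(out_cols) + 1L]] <- sig[, src, drop = FALSE] %*% t(W)
    out_dirs[[length(out_dirs) + 1L]] <- nd
    out_bvals <- c(out_bvals, rep(b, nrow(nd)))
  }
  newsig <- do.call(cbind, out_cols)
  structure(
    list(
      signal = array(newsig, dim = c(d3, length(out_bvals))),
      directions = do.call(rbind, out_dirs), bvals = out_bvals,
      spacing = img$spacing, origin = img$origin
    ),
    class = "hardi_image"
  )
}

#' Weighted, optionally mirror-symmetrized population average
#'
#' Voxelwise weighted mean of co-registered images, `sum(w_i I_i) /
#' sum(w_i)`; weights are typically the inverse tracer intensity so tracer-
#' dominated data do not bias the template, and zero-weight voxels (missing
#' tissue) are excluded from the mean. With `mirror = TRUE` each input also
#' contributes its x-mirrored counterpart, making the result exactly
#' mirror-invariant; HARDI inputs have their direction volumes permuted to
#' the mirrored directions.
#'
#' @param images List of [voxel_grid]s (all on one grid) or `hardi_image`s.
#' @param weights Optional list of non-negative weight [voxel_grid]s (or
#'   arrays), one per image; `NULL` means uniform weights.
#' @param mirror Logical: symmetrize across the mid-sagittal plane.
#' @param x_mid Mirror plane (defaults to the grid's world center).
#' @return The averaged image (same class as the inputs).
#' @export
symmetrize_population <- function(images, weights = NULL, mirror = FALSE,
                                  x_mid = NULL) {
  if (length(images) == 0L) stop("no images")
  hardi <- inherits(images[[1]], "hardi_image")
  get_w <- function(i) {
    if (is.null(weights)) return(NULL)
    w <- weights[[i]]
    if (inherits(w, "voxel_grid")) w <- w$data
    if (any(w < 0)) stop("weights must be non-negative")
    w
  }
  if (hardi) {
    ref <- images[[1]]
    grid0 <- voxel_grid(array(0, dim(ref$signal)[1:3]), ref$spacing, ref$origin)
    if (is.null(x_mid)) x_mid <- grid_x_mid(grid0)
    perm <- mirror_direction_permutation(ref$directions)
    num <- array(0, dim = dim(ref$signal))
    den <- array(0, dim = dim(ref$signal)[1:3])
    add <- function(sig4, w) {
      if (is.null(w)) w <- array(1, dim = dim(sig4)[1:3])
      for (j in seq_len(dim(sig4)[4])) {
        num[, , , j] <<- num[, , , j] + w * sig4[, , , j]
      }
      den <<- den + w
    }
    for (i in seq_along(images)) {
      im <- images[[i]]
      add(im$signal, get_w(i))
      if (mirror) {
        w <- get_w(i)
        wm <- if (is.null(w)) NULL else {
          mirror_x(voxel_grid(w, ref$spacing, ref$origin), x_mid = x_mid)$data
        }
        sigm <- array(0, dim = dim(im$signal))
        for (j in seq_len(dim(im$signal)[4])) {
          mv <- mirror_x(
            voxel_grid(im$signal[, , , j], ref$spacing, ref$origin),
            x_mid = x_mid
          )
          sigm[, , , perm[j]] <- mv$data
        }
        add(sigm, wm)
      }
    }
    zero <- den == 0
    if (any(zero)) {
      message(sprintf("symmetrize_population: %d zero-weight voxels fall back to the unweighted mean", sum(zero)))
    }
    out <- num
    k_inputs <- length(images) * (1L + mirror)
    for (j in seq_len(dim(out)[4])) {
      ch <- out[, , , j]
      ch[!zero] <- ch[!zero] / den[!zero]
      if (any(zero)) {
        um <- array(0, dim = dim(den))
        for (i in seq_along(images)) {
          um <- um + images[[i]]$signal[, , , j]
        }
        ch[zero] <- um[zero] / length(images)
      }
      out[, , , j] <- ch
    }
    res <- ref
    res$signal <- out
    return(res)
  }
  ref <- images[[1]]
  if (is.null(x_mid)) x_mid <- grid_x_mid(ref)
  num <- array(0, dim = dim(ref$data))
  den <- array(0, dim = dim(ref$data))
  for (i in seq_along(images)) {
    im <- images[[i]]
    if (!identical(dim(im$data), dim(ref$data))) stop("image grids differ")
    w <- get_w(i) %||% array(1, dim = dim(ref$data))
    num <- num + w * im$data
    den <- den + w
    if (mirror) {
      imm <- mirror_x(im, x_mid = x_mid)
      wm <- mirror_x(voxel_grid(w, ref$spacing, ref$origin), x_mid = x_mid)$data
      num <- num + wm * imm$data
      den <- den + wm
    }
  }
  zero <- den == 0
  out <- num
  out[!zero] <- num[!zero] / den[!zero]
  if (any(zero)) {
    message(sprintf("symmetrize_population: %d zero-weight voxels fall back to the unweighted mean", sum(zero)))
    um <- Reduce(`+`, lapply(images, function(im) im$data)) / length(images)
    if (mirror) {
      umm <- Reduce(`+`, lapply(images, function(im) {
        mirror_x(im, x_mid = x_mid)$data
      })) / length(images)
      um <- (um + umm) / 2
    }
    out[zero] <- um[zero]
  }
  voxel_grid(out, ref$spacing, ref$origin)
}

# index permutation sending each direction to its x-mirrored counterpart
#' @noRd
mirror_direction_permutation <- function(dirs, tol_deg = 1) {
  md <- mirror_dir(dirs)
  ca <- abs(md %*% t(dirs))
  perm <- max.col(ca, ties.method = "first")
  worst <- acos(pmin(1, ca[cbind(seq_len(nrow(dirs)), perm)])) * 180 / pi
  if (max(worst) > tol_deg) {
    stop(sprintf(
      "direction set is not mirror-symmetric (worst mismatch %.2f deg)", max(worst)
    ))
  }
  perm
}
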