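test_that("slab symmetry forces an exactly constant direction field (both methods)", {
  s <- slab_fixture()
  dom <- s$df$domain
  expect_lt(max(abs(s$df$field[, , , 1][dom])), 1e-5)
  expect_lt(max(abs(s$df$field[, , , 2][dom])), 1e-5)
  expect_equal(min(s$df$field[, , , 3][dom]), 1, tolerance = 1e-9)
  dfv <- compute_direction_field(s$ct$cortex, method = "vector")
  expect_lt(max(abs(dfv$field[, , , 1][dom])), 1e-6)
  expect_gt(min(dfv$field[, , , 3][dom]), 1 - 1e-9)
})

test_that("shell direction field tracks the analytic radial field", {
  s <- small_shell()
  dom <- which(s$df$domain, arr.ind = TRUE) - 1L
  w <- voxel_to_world(s$ct$cortex$interior, dom)
  rad <- w / sqrt(rowSums(w^2))
  v <- sapply(1:3, function(c_) s$df$field[, , , c_][s$df$domain])
  ang <- acos(pmin(1, abs(rowSums(rad * v)))) * 180 / pi
  expect_lt(median(ang), 5)
  # orientation: inner -> outer, i.e. along +radius
  expect_gt(mean(rowSums(rad * v) > 0), 0.99)
})

test_that("trajectories integrate straight through a slab and radially through a shell", {
  s <- slab_fixture()
  tr <- trace_trajectory(c(1500, 1500, 0), s$df, s$ct$cortex)
  expect_true(tr$ok)
  expect_equal(max(tr$arclen), 1000, tolerance = 25 / 1000 * 3)
  expect_lt(max(abs(tr$points[, 1] - 1500)), 1e-6)
  sh <- small_shell()
  # start at the inner-boundary voxel nearest the patch center
  g <- sh$ct$cortex$interior
  ib <- which(sh$ct$cortex$inner_boundary$data > 0, arr.ind = TRUE) - 1L
  w <- voxel_to_world(g, ib)
  uv <- sh$ct$flat_fn(w)
  start <- w[which.min((uv[, 1] - 0.5)^2 + (uv[, 2] - 0.5)^2), ]
  tr2 <- trace_trajectory(start, sh$df, sh$ct$cortex)
  expect_true(tr2$ok)
  # length close to the shell thickness (boundary voxel quantization allowed)
  expect_lt(abs(max(tr2$arclen) - 600), 90)
  # halving the step moves the endpoint by less than one voxel
  tr3 <- trace_trajectory(start, sh$df, sh$ct$cortex, step = 15)
  endpoint_shift <- sqrt(sum((tr2$points[nrow(tr2$points), ] - tr3$points[nrow(tr3$points), ])^2))
  expect_lt(endpoint_shift, 60)
  expect_error(trace_trajectory(start, sh$df, sh$ct$cortex, step = 100), "half the voxel")
})

test_that("flatmap stack recovers analytic depth and flatmap coordinates", {
  x <- small_shell_stack()
  ct <- x$ct
  fw <- x$fs$from_world$data
  def <- !is.na(fw[, , , 3]) & ct$cortex$interior$data > 0
  vox <- which(def, arr.ind = TRUE) - 1L
  wpts <- voxel_to_world(ct$cortex$interior, vox)
  derr <- abs(fw[, , , 3][def] - ct$depth_fn(wpts))
  expect_lt(mean(derr), 0.05)
  uvtrue <- ct$flat_fn(wpts)
  uverr <- sqrt(((fw[, , , 1][def] - uvtrue[, 1]) * 119)^2 +
    ((fw[, , , 2][def] - uvtrue[, 2]) * 119)^2)
  expect_lt(mean(uverr), 2) # in stack voxels of the 120 x 120 in-plane grid
  # construction is deterministic (no RNG)
  fs2 <- build_flatstack(ct$cortex, x$df, dims = c(120L, 120L, 20L))
  expect_identical(fs2$from_world$data, x$fs$from_world$data)
  expect_error(
    build_flatstack(ct$cortex, x$df, dims = c(12L, 12L, 4L), max_fail = 0.0001),
    "failed"
  )
})

test_that("volume-to-stack mapping composes with the depth oracle", {
  x <- small_shell_stack()
  ct <- x$ct
  g <- ct$cortex$interior
  const <- voxel_grid(array(7, dim(g$data)), g$spacing, g$origin)
  st <- map_to_stack(const, x$fs)
  valid <- !is.na(x$fs$to_world[, , , 1])
  expect_lt(max(abs(st$data[valid] - 7)), 1e-9)
  depvol <- voxel_grid(
    array(ct$depth_fn(grid_coordinates(g)), dim(g$data)),
    g$spacing, g$origin
  )
  std <- map_to_stack(depvol, x$fs)
  D <- x$fs$dims[3]
  for (z in c(3, 10, 17)) {
    lay <- std$data[, , z][valid[, , z]]
    expect_lt(mean(abs(lay - (z - 1) / (D - 1))), 0.02)
    expect_lt(quantile(abs(lay - (z - 1) / (D - 1)), 0.99), 0.05)
  }
})

test_that("stack points map to world and back within one stack voxel", {
  x <- small_shell_stack()
  pts <- as.matrix(expand.grid(seq(30, 90, 15), seq(30, 90, 15), c(4, 10, 16)))
  w <- map_points_from_stack(pts, x$fs)
  back <- stack_coords_of_world(x$fs, w$points)
  err <- sqrt(rowSums((back - pts)^2))
  expect_lt(median(err), 1)
  expect_lt(max(err), 2.5)
  # mid-depth layer lands at the mid radius
  mid <- map_points_from_stack(cbind(seq(40, 80, 10), 60, (x$fs$dims[3] - 1) / 2), x$fs)
  expect_lt(max(abs(sqrt(rowSums(mid$points^2)) - 900)), 60)
  expect_error(map_points_from_stack(cbind(-5, 0, 0), x$fs), "out of bounds")
})

test_that("flat projections reduce over depth as specified", {
  a <- array(0, c(4, 5, 3))
  a[2, 3, 2] <- 4
  expect_equal(flat_projection(a, "max")[2, 3], 4)
  expect_equal(sum(flat_projection(a, "sum")), sum(a))
  set.seed(30)
  b <- array(runif(60), c(4, 5, 3))
  expect_true(all(flat_projection(b, "max") >= flat_projection(b, "mean")))
})

test_that("isotropy validation scores a near-isometric slab stack at ~1", {
  x <- slab_stack()
  rep_ <- isotropy_validate(x$fs,
    layers = c(3L, 10L, 17L), seed_spacing = 6L,
    radius = 150, seed = 2
  )
  expect_gt(nrow(rep_$seeds), 50)
  expect_true(all(rep_$seeds$score >= 0.95))
  expect_true(all(rep_$seeds$score <= 1))
  expect_true(all(rep_$seeds$lambda1 >= rep_$seeds$lambda3))
})

test_that("a known 2x uniaxial stretch scores exactly 0.5 and is radius-invariant", {
  A <- diag(c(1 / 50, 1 / 50, 2 / 50)) # world um -> stack voxels, z stretched 2x
  fs <- affine_stack(A)
  for (r in c(100, 200, 400)) {
    rep_ <- isotropy_validate(fs,
      layers = c(10L), seed_spacing = 10L,
      radius = r, n_sphere_samples = 400, seed = 3
    )
    expect_gt(nrow(rep_$seeds), 5)
    expect_equal(mean(rep_$seeds$score), 0.5, tolerance = 0.02)
    expect_true(all(rep_$seeds$score >= 0 & rep_$seeds$score <= 1))
  }
  iso <- affine_stack(diag(c(1 / 50, 1 / 50, 1 / 50)))
  rep_iso <- isotropy_validate(iso, layers = c(10L), seed_spacing = 10L, radius = 150, seed = 4)
  expect_true(all(rep_iso$seeds$score >= 0.95))
})
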