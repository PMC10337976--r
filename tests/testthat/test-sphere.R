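test_that("a single direction relaxes to an antipodal pair with closed-form energy", {
  ds <- optimize_symmetric_directions(1, seed = 0)
  expect_equal(nrow(ds$directions), 1L)
  expect_equal(sqrt(sum(ds$directions^2)), 1, tolerance = 1e-9)
  # two antipodal charges at distance 2: energy exactly 1/2
  expect_equal(ds$energy, 0.5, tolerance = 1e-12)
  expect_equal(direction_energy(ds$directions), 0.5, tolerance = 1e-12)
})

test_that("n = 3 recovers the orthogonal (octahedral) optimum", {
  ds <- optimize_symmetric_directions(3, seed = 0)
  expect_equal(min_pairwise_angle(ds$directions), 90, tolerance = 1)
  oct_energy <- 12 / sqrt(2) + 3 / 2 # octahedron: 12 edges + 3 diameters
  expect_equal(ds$energy, oct_energy, tolerance = 1e-4)
  # brute-force oracle: no random mirror-symmetric configuration does better
  set.seed(40)
  for (i in 1:100) {
    x <- rnorm(3)
    x <- x / sqrt(sum(x^2))
    th <- runif(1, 0, 2 * pi)
    cand <- rbind(x, c(-x[1], x[2:3]), c(0, cos(th), sin(th)))
    expect_gte(direction_energy(cand), ds$energy - 1e-8)
  }
  # the optimum is rotation-degenerate but seed-stable in its invariants
  ds2 <- optimize_symmetric_directions(3, seed = 99)
  expect_equal(ds2$energy, ds$energy, tolerance = 1e-6)
  expect_equal(min_pairwise_angle(ds2$directions), 90, tolerance = 1)
})

test_that("direction optimization enforces exact symmetry closures and monotone energy", {
  ds <- optimize_symmetric_directions(16, seed = 1)
  expect_equal(nrow(ds$directions), 16L)
  expect_true(all(abs(sqrt(rowSums(ds$directions^2)) - 1) < 1e-12))
  md <- ds$directions
  md[, 1] <- -md[, 1]
  # every mirrored representative coincides with a representative (up to antipode)
  match_cos <- apply(abs(md %*% t(ds$directions)), 1, max)
  expect_true(all(match_cos > 1 - 1e-12))
  # representatives pairwise distinct up to antipodal equivalence
  ca <- abs(ds$directions %*% t(ds$directions))
  diag(ca) <- 0
  expect_lt(max(ca), 1 - 1e-6)
  expect_true(all(diff(ds$energy_trace) <= 1e-12))
})

test_that("spherical interpolation reproduces constants and identities", {
  ds <- optimize_symmetric_directions(16, seed = 2)
  hi <- make_hardi_phantom(c(3, 3, 3), ds$directions, rep(1000, 16), diag(3) * 7e-4, S0 = 50)
  # constant per shell in, constant out (partition of unity)
  out <- spherical_interpolate(hi, optimize_symmetric_directions(8, seed = 3))
  expect_equal(max(abs(out$signal - out$signal[1, 1, 1, 1])), 0, tolerance = 1e-9)
  # identical direction sets: identity within 1e-6 relative
  out2 <- spherical_interpolate(hi, ds$directions)
  expect_lt(max(abs(out2$signal - hi$signal) / hi$signal), 1e-6)
  # commutes with per-shell scaling
  hi2 <- hi
  hi2$signal <- hi$signal * 3
  out3 <- spherical_interpolate(hi2, ds$directions[1:5, ])
  out4 <- spherical_interpolate(hi, ds$directions[1:5, ])
  expect_equal(out3$signal, out4$signal * 3, tolerance = 1e-12)
  expect_error(
    spherical_interpolate(hi, c(1, 0, 0), max_gap = 1e-4),
    "deg from the nearest"
  )
})

test_that("tensor-signal interpolation 128 -> 64 stays under 2% relative RMSE", {
  D <- diag(c(1.5e-3, 3e-4, 3e-4))
  src <- optimize_symmetric_directions(128, seed = 5)
  dst <- optimize_symmetric_directions(64, seed = 0)
  hi <- make_hardi_phantom(c(3, 3, 3), src$directions, rep(1000, 128), tensor = D)
  truth <- make_hardi_phantom(c(3, 3, 3), dst$directions, rep(1000, 64), tensor = D)
  out <- spherical_interpolate(hi, dst)
  rel_rmse <- sqrt(mean((out$signal - truth$signal)^2)) / mean(truth$signal)
  expect_lt(rel_rmse, 0.02)
})

test_that("population averaging: convexity, mirror projection, tracer suppression", {
  set.seed(41)
  g1 <- voxel_grid(array(runif(8^3, 1, 2), c(8, 8, 8)), 50)
  g2 <- voxel_grid(array(runif(8^3, 1, 2), c(8, 8, 8)), 50)
  w1 <- voxel_grid(array(runif(8^3), c(8, 8, 8)), 50)
  # identical inputs, any weights -> that input
  same <- symmetrize_population(list(g1, g1), weights = list(w1, w1))
  expect_equal(same$data, g1$data)
  # mirror on: exactly mirror-invariant, and a projection
  m1 <- symmetrize_population(list(g1), mirror = TRUE)
  expect_equal(mirror_x(m1)$data, m1$data)
  m2 <- symmetrize_population(list(m1), mirror = TRUE)
  expect_equal(m2$data, m1$data, tolerance = 1e-12)
  # inverse-tracer weights suppress a bright blob below its unweighted level
  tracer <- array(0, c(8, 8, 8))
  tracer[3:5, 3:5, 3:5] <- 10
  bright <- voxel_grid(g1$data + tracer, c(50, 50, 50))
  wts <- list(
    voxel_grid(1 / (1 + tracer), c(50, 50, 50)),
    voxel_grid(array(1, c(8, 8, 8)), c(50, 50, 50))
  )
  wavg <- symmetrize_population(list(bright, g2), weights = wts)
  uavg <- symmetrize_population(list(bright, g2))
  blob <- tracer > 0
  expect_true(all(wavg$data[blob] < uavg$data[blob]))
  # zero-weight voxels fall back to the unweighted mean with a message
  w0 <- voxel_grid(array(0, c(8, 8, 8)), 50)
  expect_message(
    z <- symmetrize_population(list(g1, g2), weights = list(w0, w0)),
    "zero-weight"
  )
  expect_equal(z$data, (g1$data + g2$data) / 2)
})

test_that("HARDI mirror-averaging permutes direction volumes consistently", {
  ds <- optimize_symmetric_directions(8, seed = 6)
  hi <- make_hardi_phantom(c(6, 4, 4), ds$directions, rep(1000, 8), diag(c(1.5e-3, 3e-4, 3e-4)))
  hi$signal[1:3, , , ] <- hi$signal[1:3, , , ] * 1.5 # make it spatially asymmetric
  avg <- symmetrize_population(list(hi), mirror = TRUE)
  # mirroring space and flipping direction indices leaves the average fixed
  perm <- sapply(seq_len(8), function(j) {
    md <- ds$directions[j, ] * c(-1, 1, 1)
    which.max(abs(ds$directions %*% md))
  })
  g0 <- voxel_grid(array(0, c(6, 4, 4)), hi$spacing, hi$origin)
  for (j in 1:8) {
    mirrored <- mirror_x(voxel_grid(avg$signal[, , , j], hi$spacing, hi$origin))
    expect_equal(mirrored$data, avg$signal[, , , perm[j]], tolerance = 1e-9)
  }
})
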