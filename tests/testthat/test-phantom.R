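test_that("shell cortex has the analytic thickness along radial rays", {
  ct <- small_shell()$ct
  g <- ct$cortex$interior
  co <- grid_coordinates(g)
  inside <- g$data > 0
  set.seed(10)
  # sample rays through the patch center region and count interior voxels
  for (i in 1:5) {
    lon <- runif(1, -0.6, 0.6)
    lat <- runif(1, -0.6, 0.6)
    d <- c(cos(lat) * cos(lon), cos(lat) * sin(lon), sin(lat))
    rr <- seq(500, 1300, by = 20)
    pts <- outer(rr, d)
    v <- sample_volume(g, pts, mode = "nearest")
    run_um <- sum(v > 0) * 20
    expect_gt(run_um, 600 - 90)
    expect_lt(run_um, 600 + 90)
  }
  # one-voxel-thick boundary sheets on opposite sides of the interior
  expect_true(mask_count(ct$cortex$inner_boundary) > 0)
  expect_true(mask_count(ct$cortex$outer_boundary) > mask_count(ct$cortex$inner_boundary))
})

test_that("shell depth is 0.5 exactly at mid-surface and flatmap is injective", {
  ct <- small_shell()$ct
  expect_equal(
    ct$depth_fn(ct$cortex$mid_surface$vertices),
    rep(0.5, nrow(ct$cortex$mid_surface$vertices))
  )
  uv <- ct$flat_fn(ct$cortex$mid_surface$vertices)
  expect_equal(nrow(unique(round(uv, 10))), nrow(uv))
  expect_true(all(uv >= -1e-9 & uv <= 1 + 1e-9))
})

test_that("shell generator rejects degenerate geometry", {
  expect_error(make_shell_cortex(1000, 2000, spacing = 400), "spacing too coarse")
  expect_error(
    make_shell_cortex(patch = c(-1, 1, -1.5, 1.56)),
    "poles"
  )
})

test_that("STPT phantom: no fibers means no tracer difference outside the injection", {
  ph0 <- make_stpt_phantom(
    injection = list(center = c(1600, 1600, 1600), radius = 400),
    n_fibers = 0, seed = 8
  )
  outside <- !(ph0$truth$injection$data > 0)
  d <- (ph0$channels$data[, , , 2] - ph0$channels$data[, , , 1])[outside]
  # only multiplicative noise remains: bounded by a few noise sd of background
  noise_sd <- ph0$truth$noise_sd * ph0$truth$levels["background"] * sqrt(2)
  expect_lt(max(abs(d)), 6 * noise_sd)
  expect_error(
    make_stpt_phantom(injection = list(center = c(0, 0, 0), radius = 10), n_fibers = -1),
    "n_fibers"
  )
})

test_that("every planted cell center is a 26-neighborhood local maximum of channel 3", {
  ph <- stpt_fixture()
  ch3 <- ph$channels$data[, , , 3]
  g <- ph$channels
  vi <- round(world_to_voxel(g, ph$truth$cells$points))
  d3 <- dim(ch3)
  for (i in seq_len(nrow(vi))) {
    x <- vi[i, 1] + 1; y <- vi[i, 2] + 1; z <- vi[i, 3] + 1
    nb <- ch3[(x - 1):(x + 1), (y - 1):(y + 1), (z - 1):(z + 1)]
    expect_equal(max(nb), nb[2, 2, 2])
  }
})

test_that("phantom generators are deterministic given a seed", {
  a <- make_stpt_phantom(injection = list(center = c(1600, 1600, 1600), radius = 400), seed = 5)
  b <- make_stpt_phantom(injection = list(center = c(1600, 1600, 1600), radius = 400), seed = 5)
  expect_identical(a$channels$data, b$channels$data)
  expect_identical(a$truth$cells$points, b$truth$cells$points)
  img <- matrix(runif(300 * 200), 300, 200)
  t1 <- make_tileset(img, 100, 20, noise_sd = 0.01, seed = 6)
  t2 <- make_tileset(img, 100, 20, noise_sd = 0.01, seed = 6)
  expect_identical(t1$tiles, t2$tiles)
  g <- voxel_grid(array(0, c(10, 10, 10)), c(100, 100, 100))
  tr1 <- make_tractogram_phantom(4, "helix", rbind(c(0, 0, 0), c(900, 900, 900)), g, seed = 7)
  tr2 <- make_tractogram_phantom(4, "helix", rbind(c(0, 0, 0), c(900, 900, 900)), g, seed = 7)
  expect_identical(tr1$streamlines, tr2$streamlines)
})

test_that("tileset covers the image losslessly and with the closed-form tile count", {
  img <- matrix(100 + sin(outer(1:500, 1:330) / 97), 500, 330)
  ts <- make_tileset(img, tile_size = 120, overlap = 30, vignette = NULL, noise_sd = 0)
  count <- function(n) ceiling((n - 30) / (120 - 30))
  expect_length(ts$tiles, count(500) * count(330))
  # reassemble by offsets
  rec <- matrix(NA_real_, 500, 330)
  for (i in seq_along(ts$tiles)) {
    px <- round(ts$offsets[i, 1:2] / ts$pitch)
    rec[px[1] + 1:120, px[2] + 1:120] <- ts$tiles[[i]]
  }
  expect_equal(rec, img)
  # image smaller than a tile: single-tile set
  small <- make_tileset(matrix(1, 50, 40), tile_size = 120, overlap = 30)
  expect_length(small$tiles, 1L)
  expect_error(make_tileset(img, 100, 60), "overlap")
})

test_that("single-tensor HARDI phantom matches its closed form", {
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0) / sqrt(2))
  iso <- make_hardi_phantom(c(3, 3, 3), dirs, rep(1000, 4), diag(3) * 7e-4)
  s <- matrix(iso$signal, ncol = 4)
  expect_equal(max(apply(s, 1, sd)), 0)
  prol <- make_hardi_phantom(c(2, 2, 2), dirs, rep(1000, 4), diag(c(1.5e-3, 2e-4, 2e-4)))
  sig <- matrix(prol$signal, ncol = 4)[1, ]
  expect_equal(which.min(sig), 1L)
  b0 <- make_hardi_phantom(c(2, 2, 2), dirs, rep(0, 4), diag(c(1.5e-3, 2e-4, 2e-4)), S0 = 73)
  expect_true(all(b0$signal == 73))
  expect_error(
    make_hardi_phantom(c(2, 2, 2), dirs, rep(1000, 4), diag(c(-1, 1, 1) * 1e-3)),
    "positive definite"
  )
})

test_that("tractogram phantom emits exact voxel oracles for straight lines", {
  g <- voxel_grid(array(0, c(15, 12, 9)), c(80, 80, 80))
  bb <- rbind(c(0, 0, 0), c(14, 11, 8) * 80)
  t0 <- make_tractogram_phantom(0, "straight", bb, g)
  expect_length(t0$streamlines, 0L)
  tr <- make_tractogram_phantom(6, "straight", bb, g, seed = 11)
  for (i in 1:6) {
    vox <- tr$metadata$voxels[[i]]
    expect_equal(nrow(vox), 15L) # the full x row
    expect_length(unique(vox[, 2]), 1L)
    expect_length(unique(vox[, 3]), 1L)
    # polyline stays on that row
    p <- tr$streamlines[[i]]
    expect_equal(unique(p[, 2]), vox[1, 2] * 80, ignore_attr = TRUE)
  }
})
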