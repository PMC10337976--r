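test_that("injection site is recovered from the phantom blob with high overlap", {
  ph <- stpt_fixture()
  ch3 <- voxel_grid(ph$channels$data[, , , 3], ph$channels$spacing, ph$channels$origin)
  site <- locate_injection_site(ch3)
  expect_gte(dice(site$mask, ph$truth$injection), 0.7)
  expect_equal(mask_count(site$mask) * prod(ch3$spacing) / 1e9, site$volume_mm3)
  # centroid close to the planted center
  expect_lt(sqrt(sum((site$centroid - c(1600, 1600, 1600))^2)), 2 * 50)
  # invariance to uniform intensity rescaling
  ch3b <- ch3
  ch3b$data <- ch3$data * 3.7
  site2 <- locate_injection_site(ch3b)
  expect_identical(site2$mask$data, site$mask$data)
})

test_that("only the brightest of two blobs survives the half-max threshold", {
  a <- array(0, c(40, 40, 20))
  g <- voxel_grid(a, c(50, 50, 50))
  co <- grid_coordinates(g)
  d1 <- sqrt(rowSums(sweep(co, 2, c(500, 500, 500), "-")^2))
  d2 <- sqrt(rowSums(sweep(co, 2, c(1500, 1500, 500), "-")^2))
  a[] <- 100 * (d1 < 200) + 40 * (d2 < 200) # second blob at 40% brightness
  g$data <- a
  site <- locate_injection_site(g)
  vox <- which(site$mask$data > 0, arr.ind = TRUE) - 1L
  w <- voxel_to_world(g, vox)
  expect_lt(max(sqrt(rowSums(sweep(w, 2, c(500, 500, 500), "-")^2))), 400)
  expect_error(locate_injection_site(voxel_grid(array(0, c(4, 4, 4)), 50)), "no injection signal")
  expect_message(locate_injection_site(voxel_grid(array(1, c(6, 6, 6)), 50)), "degenerate")
})

test_that("peak extraction finds exactly the planted maxima", {
  g <- voxel_grid(array(0, c(21, 21, 9)), c(50, 50, 50))
  ctr <- voxel_to_world(g, cbind(10, 10, 4))[1, ]
  d2 <- rowSums(sweep(grid_coordinates(g), 2, ctr, "-")^2)
  sm <- voxel_grid(array(0.9 * exp(-d2 / (2 * 100^2)), c(21, 21, 9)), c(50, 50, 50))
  pk <- extract_peaks(sm)
  expect_equal(nrow(pk$points), 1L)
  expect_equal(pk$points[1, ], voxel_to_world(g, cbind(10, 10, 4))[1, ])
  expect_equal(pk$value, 0.9)
  # everything below threshold: empty set
  low <- voxel_grid(array(0.4, c(5, 5, 5)), 50)
  low$data[3, 3, 3] <- 0.45
  expect_equal(nrow(extract_peaks(low)$points), 0L)
  expect_error(extract_peaks(voxel_grid(array(2, c(3, 3, 3)), 50)), "\\[0, 1\\]")
})

test_that("peak extraction is invariant under crossing-preserving monotone transforms", {
  ph <- stpt_fixture()
  ch3 <- ph$channels$data[, , , 3]
  pm <- voxel_grid(ch3 / max(ch3), ph$channels$spacing, ph$channels$origin)
  pk1 <- extract_peaks(pm, min_separation = 100)
  warp <- function(p) p^2 / (p^2 + (1 - p)^2) # monotone, fixes 0.5
  pm2 <- pm
  pm2$data <- warp(pm$data)
  pk2 <- extract_peaks(pm2, min_separation = 100)
  expect_equal(pk1$points, pk2$points)
})

test_that("phantom cell spots are recovered with >= 0.95 recall and precision", {
  ph <- stpt_fixture()
  ch3 <- ph$channels$data[, , , 3]
  pm <- voxel_grid(ch3 / max(ch3), ph$channels$spacing, ph$channels$origin)
  pk <- extract_peaks(pm, p_min = 0.5, min_separation = 100)
  truth <- ph$truth$cells$points
  tol <- 1.5 * 50
  prec <- mean(vapply(seq_len(nrow(pk$points)), function(i) {
    min(sqrt(rowSums(sweep(truth, 2, pk$points[i, ], "-")^2))) < tol
  }, logical(1)))
  rec <- mean(vapply(seq_len(nrow(truth)), function(i) {
    min(sqrt(rowSums(sweep(pk$points, 2, truth[i, ], "-")^2))) < tol
  }, logical(1)))
  expect_gte(prec, 0.95)
  expect_gte(rec, 0.95)
})

test_that("intensity-threshold tracer segmentation behaves and nests in k_sd", {
  ph <- stpt_fixture()
  ch1 <- voxel_grid(ph$channels$data[, , , 1], ph$channels$spacing, ph$channels$origin)
  ch2d <- ph$channels$data[, , , 2]
  empty <- segment_tracer_by_intensity(ch1, ch1$data, k_sd = 4)
  expect_equal(mask_count(empty), 0L)
  seg3 <- segment_tracer_by_intensity(ch1, ch2d, k_sd = 3, injection = ph$truth$injection)
  seg4 <- segment_tracer_by_intensity(ch1, ch2d, k_sd = 4, injection = ph$truth$injection)
  expect_true(all(seg4$data <= seg3$data)) # threshold nesting
  # recall over truth fibers outside the dilated injection exclusion zone
  excl <- segment_tracer_by_intensity(ch1, ch2d, k_sd = 4, injection = ph$truth$injection, dilate = 2)
  tm <- ph$truth$tracer$data > 0
  co <- grid_coordinates(ch1)
  far <- array(sqrt(rowSums(sweep(co, 2, c(1600, 1600, 1600), "-")^2)) > 400 + 3 * 50, dim(tm))
  scored <- tm & far
  expect_gte(sum(excl$data > 0 & scored) / sum(scored), 0.9)
  expect_error(segment_tracer_by_intensity(ch1, ch2d[1:10, , ]), "shapes differ")
})

test_that("tracer density conserves positive-pixel counts into 50 um bins", {
  set.seed(20)
  secs <- lapply(1:4, function(i) matrix(rbinom(120 * 90, 1, 0.1), 120, 90))
  den <- tracer_density(secs, pitch = c(1.385, 1.339), section_pitch = 50, out_spacing = 50)
  expect_equal(sum(den$data), sum(vapply(secs, sum, numeric(1))))
  expect_equal(dim(den$data)[3], 4L)
  # fully-positive section: per-bin counts are the pixel-center counts
  full <- tracer_density(list(matrix(1, 100, 100)), pitch = c(1.385, 1.339))
  expect_equal(sum(full$data), 100 * 100)
  expect_true(all(full$data >= 0))
  # single positive pixel -> one voxel with value 1
  one <- matrix(0, 60, 60)
  one[13, 29] <- 1
  d1 <- tracer_density(list(one))
  expect_equal(sum(d1$data), 1)
  expect_equal(max(d1$data), 1)
  # empty input
  expect_equal(sum(tracer_density(list(matrix(0, 10, 10)))$data), 0)
})

test_that("normalized intensity is anchored at 1 outside the injection and unclamped inside", {
  ph <- stpt_fixture()
  ch1 <- voxel_grid(ph$channels$data[, , , 1], ph$channels$spacing, ph$channels$origin)
  ch2 <- voxel_grid(ph$channels$data[, , , 2], ph$channels$spacing, ph$channels$origin)
  ni <- normalized_intensity(ch1, ch2, ph$truth$injection)
  # the maximum outside the (dilated) injection is exactly 1
  expect_equal(max(ni$data[!(ph$truth$injection$data > 0)]), 1)
  expect_gt(max(ni$data[ph$truth$injection$data > 0]), 1) # saturated blob
  expect_gt(attr(ni, "norm_constant"), 0)
  # doubling both channels leaves the normalized map unchanged
  ch1b <- ch1; ch1b$data <- 2 * ch1$data
  ch2b <- ch2; ch2b$data <- 2 * ch2$data
  ni2 <- normalized_intensity(ch1b, ch2b, ph$truth$injection)
  expect_equal(ni2$data, ni$data)
})

test_that("normalized intensity errors when there is no signal to normalize", {
  z <- voxel_grid(array(5, c(6, 6, 6)), 50)
  inj <- as_mask(array(0L, c(6, 6, 6)), 50)
  inj$data[3, 3, 3] <- 1L
  expect_error(normalized_intensity(z, z, inj), "no tracer signal")
})

test_that("combine_max is the voxelwise maximum, associative and commutative", {
  set.seed(21)
  gs <- lapply(1:3, function(i) voxel_grid(array(runif(4^3), c(4, 4, 4)), 50))
  single <- combine_max(gs[1])
  expect_equal(single$data, gs[[1]]$data)
  m123 <- combine_max(gs)
  m321 <- combine_max(rev(gs))
  expect_equal(m123$data, m321$data)
  expect_equal(m123$data, combine_max(list(combine_max(gs[1:2]), gs[[3]]))$data)
  # disjoint supports -> union
  a <- voxel_grid(array(0, c(4, 4, 4)), 50); a$data[1, 1, 1] <- 1
  b <- voxel_grid(array(0, c(4, 4, 4)), 50); b$data[4, 4, 4] <- 2
  u <- combine_max(list(a, b))
  expect_equal(sum(u$data > 0), 2)
  bad <- voxel_grid(array(0, c(5, 4, 4)), 50)
  expect_error(combine_max(list(a, bad)), "match")
})

test_that("point rasterization conserves counts and nests 100 um into 400 um", {
  set.seed(22)
  pts <- point_set(matrix(runif(3 * 500, 0, 1600), ncol = 3))
  ext <- rbind(c(0, 0, 0), c(1600, 1600, 1600))
  d100 <- rasterize_points(pts, 100, ext)
  d400 <- rasterize_points(pts, 400, ext)
  expect_equal(sum(d100$data), 500)
  expect_equal(sum(d400$data), 500)
  # block-sum the 100 um image 4x4x4 and compare
  agg <- array(0, dim(d400$data))
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    agg <- agg + d100$data[seq(i, 16, 4), seq(j, 16, 4), seq(k, 16, 4)]
  }
  expect_equal(agg, d400$data)
  expect_equal(sum(rasterize_points(point_set(matrix(numeric(0), ncol = 3)), 100, ext)$data), 0)
})

test_that("laminar labels follow relative depth with a configurable boundary", {
  ct <- small_shell()$ct
  # analytic depth stands in for the flatmap-stack depth lookup
  depth_of <- function(pts) ct$depth_fn(pts)
  cells <- point_set(rbind(
    1140 * c(1, 0, 0) / 1, # r = 1140 -> depth 0.9
    660 * c(1, 0, 0) # r = 660 -> depth 0.1
  ))
  lab <- classify_laminar(cells, depth_of)
  expect_equal(lab$label, c("supragranular", "infragranular"))
  expect_equal(unique(classify_laminar(cells, depth_of, boundary = 0)$label), "supragranular")
  expect_equal(unique(classify_laminar(cells, depth_of, boundary = 1)$label), "infragranular")
  out <- classify_laminar(point_set(matrix(c(0, 0, 0), ncol = 3)), function(p) rep(NA_real_, nrow(p)))
  expect_equal(out$label, "unassigned")
})
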