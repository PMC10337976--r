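# Shared phantom fixtures, built lazily once per test run and cached.
# The "small" shell (600-1200 um at 60 um voxels) keeps module tests fast;
# the full-scale shell (1000-2000 um at 50 um) is only built by the
# acceptance tests that need it.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

small_shell <- function() {
  fixture("small_shell", function() {
    ct <- make_shell_cortex(r_inner = 600, r_outer = 1200, spacing = 60)
    df <- compute_direction_field(ct$cortex)
    list(ct = ct, df = df)
  })
}

small_shell_stack <- function() {
  fixture("small_shell_stack", function() {
    s <- small_shell()
    list(
      ct = s$ct, df = s$df,
      fs = build_flatstack(s$ct$cortex, s$df, dims = c(120L, 120L, 20L))
    )
  })
}

slab_fixture <- function() {
  fixture("slab", function() {
    ct <- make_slab_cortex(thickness = 1000, extent = c(3000, 3000), spacing = 50)
    df <- compute_direction_field(ct$cortex)
    list(ct = ct, df = df)
  })
}

# isometric slab stack: 50 um per stack voxel on every axis. The depth
# axis spans the physical slab thickness (mask thickness + one voxel,
# surfaces lying half a voxel beyond the boundary voxel centers): 1050 um
# over 22 layers = 50 um per layer, matching the 50 um in-plane pitch.
slab_stack <- function() {
  fixture("slab_stack", function() {
    s <- slab_fixture()
    list(
      ct = s$ct, df = s$df,
      fs = build_flatstack(s$ct$cortex, s$df, dims = c(61L, 61L, 22L))
    )
  })
}

stpt_fixture <- function() {
  fixture("stpt", function() {
    make_stpt_phantom(
      injection = list(center = c(1600, 1600, 1600), radius = 400),
      n_fibers = 12, n_cells = 40, seed = 3
    )
  })
}

# full-scale shell; shared by the acceptance blocks only
acceptance_shell <- function() {
  fixture("acceptance_shell", function() {
    ct <- make_shell_cortex() # 1000-2000 um, 50 um voxels, 120 deg patch
    df <- compute_direction_field(ct$cortex)
    list(ct = ct, df = df)
  })
}

# synthetic flatmap stack applying a known affine map world -> stack voxel
# coordinates (used by the isotropy validation oracle tests)
affine_stack <- function(A, dims = c(61L, 61L, 21L), spacing = 50,
                         cortex_dim = c(61L, 61L, 27L),
                         cortex_origin = c(0, 0, -150)) {
  Ainv <- solve(A)
  U <- dims[1]; V <- dims[2]; D <- dims[3]
  iu <- rep(0:(U - 1), times = V * D)
  iv <- rep(rep(0:(V - 1), each = U), times = D)
  id <- rep(0:(D - 1), each = U * V)
  w <- cbind(iu, iv, id) %*% t(Ainv)
  to_world <- array(w, dim = c(U, V, D, 3L))
  g <- voxel_grid(array(0, cortex_dim), spacing, cortex_origin)
  co <- grid_coordinates(g)
  sc <- co %*% t(A)
  fw <- array(NA_real_, dim = c(cortex_dim, 3L))
  fw[, , , 1] <- sc[, 1] / (U - 1)
  fw[, , , 2] <- sc[, 2] / (V - 1)
  fw[, , , 3] <- sc[, 3] / (D - 1)
  structure(
    list(
      dims = dims, to_world = to_world,
      from_world = voxel_grid(fw, spacing, cortex_origin),
      provenance = list(synthetic_affine = TRUE)
    ),
    class = "flatmap_stack"
  )
}

expect_same_points <- function(a, b, tol = 1e-9) {
  expect_equal(as.numeric(a), as.numeric(b), tolerance = tol)
}
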