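smooth_noise_volume <- function(d = c(24L, 24L, 24L), seed = 3, sigma = 2) {
  set.seed(seed)
  arr <- array(rnorm(prod(d)), d)
  k <- myomap3d:::gaussian_kernel(sigma)
  volume3d(myomap3d:::cpp_sep_conv3(arr, d, list(k, k, k)))
}

test_that("constant volume gives a zero tensor; ramp gives a rank-1 tensor", {
  const <- volume3d(array(5, c(16, 16, 16)))
  tf <- compute_structure_tensor(const, window_size_um = 6)
  expect_lt(max(abs(tf$J)), 1e-20)

  d <- c(24L, 24L, 24L)
  ramp <- volume3d(array(rep(seq_len(d[1]), prod(d[2:3])), d))  # linear in axis 1
  tf <- compute_structure_tensor(ramp, window_size_um = 6)
  interior <- tf$J[8:17, 8:17, 8:17, ]
  jxx <- interior[, , , 1]
  expect_true(all(jxx > 0))
  # all other components vanish relative to Jxx
  for (m in 2:6) expect_lt(max(abs(interior[, , , m])) / min(jxx), 1e-10)
})

test_that("tensor field is symmetric PSD and matches a per-voxel dense eigen oracle", {
  vol <- smooth_noise_volume()
  tf <- compute_structure_tensor(vol, window_size_um = 5)
  eig <- eigendecompose_field(tf)
  tr <- eig$values[, , , 1] + eig$values[, , , 2] + eig$values[, , , 3]
  # PSD conservation: smoothing of outer products never makes lambda3 negative
  expect_gte(min(eig$values[, , , 3]), -1e-10 * max(tr))
  # descending order everywhere
  expect_true(all(eig$values[, , , 1] >= eig$values[, , , 2]))
  expect_true(all(eig$values[, , , 2] >= eig$values[, , , 3]))

  # brute-force oracle on a sample of voxels: assemble the 3x3 matrix and
  # eigen-solve it densely
  set.seed(11)
  d <- dim(vol$data)
  for (s in seq_len(50)) {
    i <- sample(d[1], 1); j <- sample(d[2], 1); k <- sample(d[3], 1)
    Jv <- tf$J[i, j, k, ]
    M <- matrix(c(Jv[1], Jv[2], Jv[3], Jv[2], Jv[4], Jv[5], Jv[3], Jv[5], Jv[6]), 3)
    ref <- eigen(M, symmetric = TRUE)
    expect_equal(eig$values[i, j, k, ], ref$values, tolerance = 1e-8)
    # orthonormal triad
    V <- matrix(eig$vectors[i, j, k, , ], 3, 3)
    expect_equal(crossprod(V), diag(3), tolerance = 1e-8)
    # eigenvectors match up to sign
    for (c in 1:3) {
      expect_equal(abs(sum(V[, c] * ref$vectors[, c])), 1, tolerance = 1e-6)
    }
  }
})

test_that("eigendecompose_field handles trivial and degenerate tensors", {
  d <- c(2L, 2L, 2L)
  J <- array(0, c(d, 6))
  J[, , , 1] <- 3; J[, , , 4] <- 2; J[, , , 6] <- 1  # diag(3, 2, 1)
  J[2, 2, 2, ] <- 0                                  # one zero tensor
  tf <- structure(list(J = J, voxel_size_um = c(1, 1, 1), margin_vox = c(0L, 0L, 0L)),
                  class = "tensor_field")
  eig <- eigendecompose_field(tf)
  expect_equal(eig$values[1, 1, 1, ], c(3, 2, 1))
  expect_equal(abs(eig$vectors[1, 1, 1, , ]), diag(3), tolerance = 1e-12)
  expect_equal(eig$values[2, 2, 2, ], c(0, 0, 0))
  expect_true(eig$degenerate[2, 2, 2])
  expect_false(eig$degenerate[1, 1, 1])

  J[1, 1, 1, 1] <- NA
  tf$J <- J
  expect_error(eigendecompose_field(tf), class = "myomap_validation_error")
})

test_that("fractional anisotropy closed form and conventions", {
  make_eig <- function(l) {
    structure(list(values = array(rep(l, each = 1), c(1, 1, 1, 3)),
                   vectors = array(diag(3), c(1, 1, 1, 3, 3)),
                   degenerate = array(FALSE, c(1, 1, 1))),
              class = "eigen_field")
  }
  expect_equal(as.numeric(fractional_anisotropy(make_eig(c(1, 1, 1)))), 0)
  expect_equal(as.numeric(fractional_anisotropy(make_eig(c(1, 0, 0)))), 1)
  expect_equal(as.numeric(fractional_anisotropy(make_eig(c(0, 0, 0)))), 0)
  expect_error(fractional_anisotropy(make_eig(c(1, 1, -1))),
               class = "myomap_validation_error")
})

test_that("FA is invariant under global intensity scaling", {
  vol <- smooth_noise_volume()
  fa1 <- fractional_anisotropy(eigendecompose_field(
    compute_structure_tensor(vol, window_size_um = 5)))
  vol2 <- volume3d(vol$data * 7.3, vol$voxel_size_um)
  fa2 <- fractional_anisotropy(eigendecompose_field(
    compute_structure_tensor(vol2, window_size_um = 5)))
  expect_equal(fa1, fa2, tolerance = 1e-10)
})

test_that("fiber_directions: null space of a two-axis grating is the third axis", {
  d <- c(4L, 4L, 4L)
  J <- array(0, c(d, 6))
  J[, , , 1] <- 1  # x (x) x + y (x) y: intensity varies in axes 1 and 2 only
  J[, , , 4] <- 1
  tf <- structure(list(J = J, voxel_size_um = c(1, 1, 1), margin_vox = c(0L, 0L, 0L)),
                  class = "tensor_field")
  fib <- fiber_directions(eigendecompose_field(tf))
  expect_true(all(fib$valid))
  expect_equal(abs(fib$v[, , , 3]), array(1, d), tolerance = 1e-12)
  # degenerate voxels carry a null direction
  J[1, 1, 1, ] <- 0
  tf$J <- J
  fib <- fiber_directions(eigendecompose_field(tf))
  expect_false(fib$valid[1, 1, 1])
  expect_equal(fib$v[1, 1, 1, ], c(0, 0, 0))
})

test_that("parallel-tube phantom recovers the tube axis almost everywhere", {
  spec <- fiber_phantom_spec(dims = c(64L, 64L, 64L), voxel_size_um = 1,
                             ha_epi_deg = 0, ha_endo_deg = 0, ia_deg = 0,
                             window_size_um = 10, seed = 5L)
  ph <- generate_fiber_phantom(spec)
  tf <- compute_structure_tensor(ph$volume, window_size_um = 10)
  fib <- fiber_directions(eigendecompose_field(tf))
  mg <- tf$margin_vox
  d <- dim(ph$volume$data)
  sel <- array(FALSE, d)
  sel[(mg[1] + 1):(d[1] - mg[1]), (mg[2] + 1):(d[2] - mg[2]),
      (mg[3] + 1):(d[3] - mg[3])] <- TRUE
  sel <- sel & fib$valid
  # HA = 0 means tubes along the circumferential axis (lattice axis 3)
  ang <- acos(pmin(abs(fib$v[, , , 3][sel]), 1)) * 180 / pi
  expect_gte(mean(ang < 2), 0.99)
})

test_that("recovered directions are equivariant under a 90-degree lattice rotation", {
  spec <- fiber_phantom_spec(dims = c(48L, 48L, 48L), voxel_size_um = 1,
                             ha_epi_deg = 30, ha_endo_deg = 30,
                             window_size_um = 8, seed = 9L)
  ph <- generate_fiber_phantom(spec)
  ha_of <- function(vol) {
    map <- compute_myomap(vol, tissue_mask = "all", window_size_um = 8)
    axial_mean_angle(map$HA)
  }
  ha0 <- ha_of(ph$volume)
  # rotate 90 deg about the radial (depth) axis: (i, j, k) -> (i, k, Nj+1-j)
  rot <- aperm(ph$volume$data, c(1, 3, 2))[, , rev(seq_len(48))]
  ha90 <- ha_of(volume3d(rot, voxel_size_um = 1))
  # rotating the texture by 90 deg shifts the recovered orientation by 90 deg
  expect_lt(ha_error(ha90, ha0 + 90), 1)
})

test_that("larger integration windows reduce orientation variance in a coherent block", {
  spec <- fiber_phantom_spec(dims = c(64L, 64L, 64L), voxel_size_um = 1,
                             ha_epi_deg = 20, ha_endo_deg = 20,
                             dispersion_deg = 12, window_size_um = 6, seed = 13L)
  ph <- generate_fiber_phantom(spec)
  disp_at <- function(w) {
    map <- compute_myomap(ph$volume, tissue_mask = "all", window_size_um = w)
    prof <- transmural_profile(map$HA, map$frame, n_bins = 1L)
    prof$dispersion_deg[1]
  }
  d1 <- disp_at(6); d2 <- disp_at(12); d3 <- disp_at(20)
  expect_gt(d1, d2)
  expect_gt(d2, d3)
})

test_that("window validation: volume must exceed the window on every axis", {
  vol <- volume3d(array(rnorm(16^3), c(16, 16, 16)), voxel_size_um = 1)
  expect_error(compute_structure_tensor(vol, window_size_um = 20),
               class = "myomap_validation_error")
  small <- volume3d(array(rnorm(16^3), c(16, 16, 16)), voxel_size_um = c(10, 1, 1))
  expect_error(compute_structure_tensor(small, window_size_um = 0.5),
               class = "myomap_validation_error")
})
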