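# Build an orientation_field directly from vectors (no pipeline) so the
# angle math is tested in isolation.
orientation_from <- function(vmat, d = c(2L, 2L, 2L)) {
  n <- prod(d)
  v <- array(NA_real_, c(d, 3L))
  for (c in 1:3) v[, , , c] <- array(rep(vmat[, c], length.out = n), d)
  structure(list(v = v, valid = array(TRUE, d), voxel_size_um = c(1, 1, 1),
                 margin_vox = c(0L, 0L, 0L)),
            class = "orientation_field")
}

full_frame <- function(d = c(2L, 2L, 2L)) {
  fit_wall_frame(volume3d(array(1, d), intensity_kind = "binary_mask"))
}

test_that("slab wall frame: constant coordinate triad, depth linear in slice index", {
  d <- c(10L, 4L, 4L)
  fr <- full_frame(d)
  expect_equal(fr$r_vec, c(1, 0, 0))
  expect_equal(fr$l_vec, c(0, 1, 0))
  expect_equal(myomap3d:::cross3(fr$c_vec, fr$l_vec), fr$r_vec)  # c x l = r
  expect_equal(sum(fr$c_vec^2), 1)
  expect_equal(fr$depth[, 1, 1], (0:9) / 9)

  # per-column depth: a column occupying slices 3..8 spans [0, 1] there
  m <- array(0, d); m[3:8, , ] <- 1; m[1:10, 1, 1] <- 1
  fr2 <- fit_wall_frame(volume3d(m, intensity_kind = "binary_mask"))
  expect_equal(fr2$depth[3:8, 2, 2], (0:5) / 5)
  expect_equal(fr2$depth[, 1, 1], (0:9) / 9)
  expect_true(is.na(fr2$depth[1, 2, 2]))

  expect_error(fit_wall_frame(volume3d(array(0, d), intensity_kind = "binary_mask")),
               class = "myomap_validation_error")
})

test_that("surface_normal frame recovers the analytic normal of a spherical shell", {
  d <- c(48L, 48L, 48L)
  ctr <- (d + 1) / 2
  co <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  r <- sqrt(rowSums((co - matrix(ctr, nrow(co), 3, byrow = TRUE))^2))
  shell <- array(r >= 10 & r <= 20, d)           # epi at outer, endo at inner
  epi <- array(r > 19 & r <= 20, d)
  endo <- array(r >= 10 & r < 11, d)
  fr <- fit_wall_frame(volume3d(shell * 1, intensity_kind = "binary_mask"),
                       mode = "surface_normal",
                       epi_mask = volume3d(epi * 1, intensity_kind = "binary_mask"),
                       endo_mask = volume3d(endo * 1, intensity_kind = "binary_mask"),
                       long_axis_hint = c(1, 0, 0))
  mid <- which(shell & array(r >= 13 & r <= 17, d))
  # analytic shell normal: radially inward from epi (pointing epi -> endo)
  nrm <- -(co[mid, ] - matrix(ctr, length(mid), 3, byrow = TRUE)) / r[mid]
  rv <- matrix(fr$r_vec, ncol = 3)[mid, ]
  ang <- acos(pmin(abs(rowSums(rv * nrm)), 1)) * 180 / pi
  expect_lt(stats::quantile(ang, 0.95), 3)
  # depth increases from epi (outer) to endo (inner)
  expect_lt(mean(fr$depth[which(shell & array(r > 18, d))]),
            mean(fr$depth[which(shell & array(r < 12, d))]))
  # triad stays orthonormal and right-handed per voxel
  cv <- matrix(fr$c_vec, ncol = 3)[mid, ]
  lv <- matrix(fr$l_vec, ncol = 3)[mid, ]
  expect_lt(max(abs(rowSums(cv * lv))), 1e-8)
  expect_lt(max(abs(rowSums(cv * rv))), 1e-8)
  cxl <- cbind(cv[, 2] * lv[, 3] - cv[, 3] * lv[, 2],
               cv[, 3] * lv[, 1] - cv[, 1] * lv[, 3],
               cv[, 1] * lv[, 2] - cv[, 2] * lv[, 1])
  expect_equal(cxl, rv, tolerance = 1e-6)

  expect_error(
    fit_wall_frame(volume3d(shell * 1, intensity_kind = "binary_mask"),
                   mode = "surface_normal"),
    class = "myomap_validation_error"
  )
})

test_that("helical angle: c -> 0, l -> 90, bisector -> 45, axially symmetric", {
  fr <- full_frame()
  cv <- fr$c_vec; lv <- fr$l_vec; rv <- fr$r_vec
  vm <- rbind(cv, lv, (cv + lv) / sqrt(2), -(cv + lv) / sqrt(2), rv)
  ha <- helical_angle(orientation_from(vm, c(5L, 1L, 1L)), full_frame(c(5L, 1L, 1L)))
  expect_equal(ha[1, 1, 1], 0)
  expect_equal(ha[2, 1, 1], 90)
  expect_equal(ha[3, 1, 1], 45)
  expect_equal(ha[4, 1, 1], 45)        # HA(-v) = HA(v)
  expect_true(is.na(ha[5, 1, 1]))      # purely radial fiber: HA undefined
})

test_that("intrusion angle: in-plane -> 0, radial -> +90, bisector -> 45; to_radial flips", {
  cvec <- full_frame()$c_vec; lv <- full_frame()$l_vec; rv <- full_frame()$r_vec
  vm <- rbind(cvec, lv, rv, (cvec + rv) / sqrt(2), -rv)
  fr5 <- full_frame(c(5L, 1L, 1L))
  ia <- intrusion_angle(orientation_from(vm, c(5L, 1L, 1L)), fr5)
  expect_equal(ia[1, 1, 1], 0)
  expect_equal(ia[2, 1, 1], 0)
  expect_equal(ia[3, 1, 1], 90)        # sign fixed by the tie-break convention
  expect_equal(ia[4, 1, 1], 45)
  expect_equal(ia[5, 1, 1], 90)        # axial: -r is the same direction
  ia2 <- intrusion_angle(orientation_from(vm, c(5L, 1L, 1L)), fr5,
                         convention = "to_radial")
  expect_equal(ia2[1, 1, 1], 90)
  expect_equal(ia2[3, 1, 1], 0)
  expect_equal(ia2[4, 1, 1], 45)
})

test_that("angle ops demand matching lattices", {
  fib <- orientation_from(rbind(c(0, 0, 1)), c(2L, 2L, 2L))
  expect_error(helical_angle(fib, full_frame(c(3L, 3L, 3L))),
               class = "myomap_validation_error")
  expect_error(intrusion_angle(fib, full_frame(c(3L, 3L, 3L))),
               class = "myomap_validation_error")
})

test_that("transmural profile: constant field, axial invariance, bin bookkeeping", {
  d <- c(20L, 6L, 6L)
  fr <- full_frame(d)
  ha <- array(30, d)
  prof <- transmural_profile(ha, fr, n_bins = 5L)
  expect_equal(prof$mean_angle_deg, rep(30, 5))
  expect_equal(prof$dispersion_deg, rep(0, 5), tolerance = 1e-6)
  expect_equal(sum(prof$n), prod(d))          # sum(n) == all valid voxels
  expect_false(any(prof$empty))

  # empty bins are marked, not reported as zero
  ha2 <- ha; ha2[1:10, , ] <- NA
  prof2 <- transmural_profile(ha2, fr, n_bins = 4L)
  expect_true(all(prof2$empty[1:2]))
  expect_true(all(is.na(prof2$mean_angle_deg[1:2])))
  expect_equal(sum(prof2$n), sum(is.finite(ha2)))

  # profile with n_bins = 1 equals the axial mean of the whole valid set
  set.seed(2)
  hr <- array(runif(prod(d), -80, 80), d)
  p1 <- transmural_profile(hr, fr, n_bins = 1L)
  expect_equal(p1$mean_angle_deg, axial_mean_angle(hr))

  expect_error(transmural_profile(array(NA_real_, d), fr, 5L),
               class = "myomap_validation_error")
})

test_that("axial statistics handle the +/-90 wrap correctly", {
  d <- c(4L, 1L, 1L)
  fr <- full_frame(d)
  th <- array(c(88, -88, 89, -89), d)   # clustered around the 90-degree axis
  p <- transmural_profile(th, fr, n_bins = 1L)
  expect_lt(ha_error(p$mean_angle_deg, 90), 1e-6)
  expect_lt(p$dispersion_deg, 2)
})

test_that("mean FA over ROIs and masks", {
  d <- c(4L, 4L, 4L)
  fa <- array(0.2, d); fa[, , 3:4] <- 0.6
  expect_equal(as.numeric(mean_fa(fa)), 0.4)
  roi <- roi_box(c(0, 0, 0), c(4, 4, 2))
  m <- mean_fa(fa, roi)
  expect_equal(as.numeric(m), 0.2)
  expect_equal(attr(m, "n_voxels"), 32L)
  expect_equal(as.numeric(mean_fa(array(0.5, d))), 0.5)
  expect_error(mean_fa(fa, roi, valid = array(FALSE, d)),
               class = "myomap_validation_error")
  expect_error(mean_fa(fa, roi_box(c(0, 0, 0), c(9, 9, 9))),
               class = "myomap_validation_error")
})

test_that("HA/IA are invariant under global sign flip of the orientation field", {
  fx <- ramp_fixture()
  fib <- fx$map$fibers
  flipped <- fib
  flipped$v <- -fib$v
  fr <- fx$map$frame
  expect_equal(helical_angle(flipped, fr), helical_angle(fib, fr))
  expect_equal(intrusion_angle(flipped, fr), intrusion_angle(fib, fr))
})
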