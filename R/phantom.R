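# Slab frame used by the fiber phantom and the default slab wall frame:
# radial r = lattice axis 1 (depth), longitudinal l = axis 2,
# circumferential c = l x r = -axis 3. Directions are axial, so the sign of
# c is immaterial for texture; it only fixes the HA sign convention.
phantom_frame_axes <- function() {
  r <- c(1, 0, 0)
  l <- c(0, 1, 0)
  list(c_vec = cross3(l, r), l_vec = l, r_vec = r)
}

# Unit direction with helical angle ha (deg) and intrusion elevation ia
# (deg) in the (c, l, r) frame.
dir_from_angles <- function(ha_deg, ia_deg, axes = phantom_frame_axes()) {
  ha <- ha_deg * pi / 180
  ia <- ia_deg * pi / 180
  outer(cos(ia) * cos(ha), axes$c_vec) +
    outer(cos(ia) * sin(ha), axes$l_vec) +
    outer(sin(ia), axes$r_vec)
}

#' Specification of a helical fiber slab phantom
#'
#' States the synthetic world the generator emulates: a transmural tissue
#' slab (depth along axis 1, epicardium at index 0) whose intensity texture
#' is a sum of soft-profile tubes laid along a depth-dependent fiber
#' direction. The helical angle ramps linearly from `ha_epi_deg` at the
#' epicardial face to `ha_endo_deg` at the endocardial face (the classical
#' +60 to -60 deg transmural transition by default) at constant intrusion
#' angle; optional per-tube angular jitter, additive Gaussian noise and
#' ring artefacts emulate disorganisation and tomographic imperfections.
#'
#' @param dims voxel triple (default 128^3).
#' @param voxel_size_um voxel size, um (default 5.8, the low-resolution
#'   scan scale).
#' @param ha_epi_deg,ha_endo_deg helical angle at depth 0 / 1, in
#'   `(-90, 90]` degrees (defaults +60 / -60).
#' @param ia_deg constant intrusion elevation (default 0: in-plane fibers).
#' @param tube_radius_vox Gaussian tube radius in voxels (default 2).
#' @param tube_density tubes per 100 voxel^2 of transmural cross-section
#'   (default 4, giving dense but resolvable texture).
#' @param dispersion_deg per-tube Gaussian angular jitter, degrees
#'   (default 0).
#' @param noise_sigma additive white Gaussian noise sd (tube amplitude is 1;
#'   default 0).
#' @param ring_amplitude additive ring-artefact amplitude (default 0).
#' @param window_size_um integration window the phantom is meant to be
#'   analysed with; dims must fit at least 5 such windows transmurally.
#' @param seed integer seed; every random draw flows from it.
#' @return A `fiber_phantom_spec`.
#' @export
fiber_phantom_spec <- function(dims = c(128L, 128L, 128L),
                               voxel_size_um = c(5.8, 5.8, 5.8),
                               ha_epi_deg = 60, ha_endo_deg = -60,
                               ia_deg = 0, tube_radius_vox = 2,
                               tube_density = 4, dispersion_deg = 0,
                               noise_sigma = 0, ring_amplitude = 0,
                               window_size_um = 123.5, seed = 1L) {
  dims <- as.integer(dims)
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
  spec <- list(
    dims = dims, voxel_size_um = as.numeric(voxel_size_um),
    ha_epi_deg = ha_epi_deg, ha_endo_deg = ha_endo_deg, ia_deg = ia_deg,
    tube_radius_vox = tube_radius_vox, tube_density = tube_density,
    dispersion_deg = dispersion_deg, noise_sigma = noise_sigma,
    ring_amplitude = ring_amplitude, window_size_um = window_size_um,
    seed = as.integer(seed)
  )
  if (any(c(spec$ha_epi_deg, spec$ha_endo_deg) <= -90) ||
      any(c(spec$ha_epi_deg, spec$ha_endo_deg) > 90)) {
    stop_validation("HA endpoints must lie in (-90, 90] degrees")
  }
  if (spec$tube_density <= 0) stop_validation("tube_density must be > 0")
  if (spec$dispersion_deg < 0 || spec$noise_sigma < 0 || spec$ring_amplitude < 0) {
    stop_validation("dispersion, noise and ring amplitudes must be nonnegative")
  }
  if (dims[1] * spec$voxel_size_um[1] < 5 * spec$window_size_um) {
    stop_validation(sprintf(
      "transmural extent (%g um) must fit at least 5 integration windows (%g um)",
      dims[1] * spec$voxel_size_um[1], spec$window_size_um
    ))
  }
  structure(spec, class = "fiber_phantom_spec")
}

#' Generate a helical fiber slab phantom with known ground truth
#'
#' Rasterises `N = round(tube_density * dims1 * dims2 / 100)` tube segments
#' with Gaussian cross-section along the depth-dependent fiber direction
#' (plus per-tube jitter of scale `dispersion_deg`), then adds noise and
#' ring artefacts. The returned ground truth is the jitter-free direction
#' field; the depth coordinate is the normalised axis-1 position.
#' Deterministic for a fixed seed.
#'
#' @param spec a [fiber_phantom_spec()].
#' @return list with `volume` ([volume3d]), `truth` (an
#'   `orientation_field` of the noiseless directions), and `depth`
#'   (3D array in `[0, 1]`).
#' @export
generate_fiber_phantom <- function(spec) {
  stopifnot(inherits(spec, "fiber_phantom_spec"))
  d <- spec$dims
  axes <- phantom_frame_axes()
  with_seed(spec$seed, {
    n_tubes <- max(1L, as.integer(round(spec$tube_density * d[1] * d[2] / 100)))
    p <- cbind(runif(n_tubes, 0, d[1] - 1),
               runif(n_tubes, 0, d[2] - 1),
               runif(n_tubes, 0, d[3] - 1))
    depth_seed <- p[, 1] / max(d[1] - 1, 1)
    ha <- spec$ha_epi_deg + (spec$ha_endo_deg - spec$ha_epi_deg) * depth_seed +
      rnorm(n_tubes, 0, spec$dispersion_deg)
    ia <- spec$ia_deg + rnorm(n_tubes, 0, spec$dispersion_deg)
    u <- dir_from_angles(ha, ia, axes)
    # long enough to always cross the lattice: no end-caps inside the volume
    # (a tube end would add gradients along the fiber axis and bias the tensor)
    hl <- 2 * max(d)
    tubes <- cbind(p, u, spec$tube_radius_vox, 1, hl)
    vol <- cpp_stamp_tubes(d, tubes)
    if (spec$noise_sigma > 0) {
      vol <- vol + array(rnorm(prod(d), 0, spec$noise_sigma), d)
    }
    if (spec$ring_amplitude > 0) {
      vol <- vol + ring_field(d, spec$ring_amplitude, ring_axis = 1L,
                              phase = runif(1, 0, 2 * pi))
    }
  })
  depth <- array(rep((seq_len(d[1]) - 1) / max(d[1] - 1, 1), prod(d[2:3])), d)
  ha_true <- spec$ha_epi_deg + (spec$ha_endo_deg - spec$ha_epi_deg) * depth
  v_true <- dir_from_angles(as.vector(ha_true), rep(spec$ia_deg, length(ha_true)), axes)
  truth <- structure(
    list(v = array(v_true, c(d, 3L)), valid = array(TRUE, d),
         voxel_size_um = spec$voxel_size_um, margin_vox = c(0L, 0L, 0L)),
    class = "orientation_field"
  )
  list(
    volume = volume3d(vol, voxel_size_um = spec$voxel_size_um),
    truth = truth,
    depth = depth
  )
}

# Concentric sinusoidal modulation about `ring_axis` through the lattice
# centre: amplitude * sin(2 pi rho / period + phase).
ring_field <- function(dims, amplitude, ring_axis = 1L, period_vox = 8,
                       phase = 0) {
  perp <- setdiff(1:3, ring_axis)
  ctr <- (dims + 1) / 2
  co <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])))
  rho <- sqrt((co[, perp[1]] - ctr[perp[1]])^2 + (co[, perp[2]] - ctr[perp[2]])^2)
  array(amplitude * sin(2 * pi * rho / period_vox + phase), dims)
}

#' Inject tomographic artefacts into a volume
#'
#' Adds white Gaussian noise and/or an additive concentric sinusoidal ring
#' modulation about `ring_axis` through the lattice centre (random phase per
#' seed) — the two imperfections structure-tensor orientation estimation is
#' known to be sensitive to. Both components are zero-mean, so intensity
#' statistics are otherwise preserved.
#'
#' @param vol a [volume3d].
#' @param noise_sigma Gaussian noise sd (>= 0).
#' @param ring_amplitude ring modulation amplitude (>= 0).
#' @param ring_axis lattice axis (1..3) the rings are concentric about.
#' @param ring_period_vox radial period of the rings in voxels (default 8).
#' @param seed integer seed.
#' @return the degraded [volume3d].
#' @export
add_artefacts <- function(vol, noise_sigma = 0, ring_amplitude = 0,
                          ring_axis = 1L, ring_period_vox = 8, seed = 1L) {
  stopifnot(is_volume3d(vol))
  if (noise_sigma < 0 || ring_amplitude < 0) {
    stop_validation("noise_sigma and ring_amplitude must be nonnegative")
  }
  d <- dim(vol$data)
  out <- vol$data
  with_seed(seed, {
    if (noise_sigma > 0) out <- out + array(rnorm(prod(d), 0, noise_sigma), d)
    if (ring_amplitude > 0) {
      out <- out + ring_field(d, ring_amplitude, ring_axis, ring_period_vox,
                              phase = runif(1, 0, 2 * pi))
    }
  })
  volume3d(out, voxel_size_um = vol$voxel_size_um)
}

#' Specification of a collagen phantom mask
#'
#' @param dims voxel triple (default 128^3).
#' @param target_fraction collagen volume fraction in `(0, 1)`.
#' @param geometry `"diffuse_streaks"` (thin scattered curvilinear fibrils,
#'   the dilated-cardiomyopathy-like pattern), `"compact_patch"` (one
#'   ellipsoidal scar-like blob, ischaemic-like), or `"mixed"`.
#' @param streak_radius_vox streak radius in voxels (default 1.5).
#' @param seed integer seed.
#' @return A `collagen_phantom_spec`.
#' @export
collagen_phantom_spec <- function(dims = c(128L, 128L, 128L), target_fraction,
                                  geometry = c("diffuse_streaks", "compact_patch", "mixed"),
                                  streak_radius_vox = 1.5, seed = 1L) {
  geometry <- match.arg(geometry)
  dims <- as.integer(dims)
  if (!is.numeric(target_fraction) || target_fraction <= 0 || target_fraction >= 1) {
    stop_validation("target_fraction must lie in (0, 1)")
  }
  structure(
    list(dims = dims, target_fraction = target_fraction, geometry = geometry,
         streak_radius_vox = streak_radius_vox, seed = as.integer(seed)),
    class = "collagen_phantom_spec"
  )
}

# Soft streak field: sum of Gaussian-profile segments with random
# orientation and length; thresholded later at the exact target count.
streak_soft_field <- function(dims, target_fraction, radius, oversample = 1.6) {
  V <- prod(dims)
  mean_len <- 0.2 * max(dims)
  n_streaks <- max(3L, as.integer(ceiling(
    oversample * target_fraction * V / (pi * radius^2 * mean_len)
  )))
  p <- cbind(runif(n_streaks, 0, dims[1] - 1),
             runif(n_streaks, 0, dims[2] - 1),
             runif(n_streaks, 0, dims[3] - 1))
  u <- matrix(rnorm(3 * n_streaks), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  hl <- runif(n_streaks, 0.05, 0.15) * max(dims)
  cpp_stamp_tubes(dims, cbind(p, u, radius, 1, hl))
}

# Soft ellipsoidal blob field centred in the middle of the lattice.
patch_soft_field <- function(dims) {
  ctr <- dims / 2 + runif(3, -0.1, 0.1) * dims
  semi <- runif(3, 0.5, 1)
  co <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])))
  q <- ((co[, 1] - ctr[1]) / semi[1])^2 + ((co[, 2] - ctr[2]) / semi[2])^2 +
    ((co[, 3] - ctr[3]) / semi[3])^2
  array(1 / (1 + q), dims)  # level sets are concentric ellipsoids
}

#' Generate a binary collagen mask with a known volume fraction
#'
#' Builds a soft structure field for the requested geometry and thresholds
#' it at exactly the voxel count matching `target_fraction`, so the achieved
#' fraction is within one voxel of the target (ties at the threshold are
#' resolved by deterministic order). Deterministic per seed.
#'
#' @param spec a [collagen_phantom_spec()].
#' @return list with `mask` (binary [volume3d]) and `achieved_fraction`
#'   (exact voxel-count ratio).
#' @export
generate_collagen_phantom <- function(spec) {
  stopifnot(inherits(spec, "collagen_phantom_spec"))
  d <- spec$dims
  V <- prod(d)
  k <- max(1L, as.integer(round(spec$target_fraction * V)))
  mask <- with_seed(spec$seed, {
    field <- switch(spec$geometry,
      diffuse_streaks = streak_soft_field(d, spec$target_fraction, spec$streak_radius_vox),
      compact_patch = patch_soft_field(d),
      mixed = {
        f1 <- streak_soft_field(d, spec$target_fraction / 2, spec$streak_radius_vox)
        f2 <- patch_soft_field(d)
        pmax(f1 / max(f1), f2 / max(f2))
      }
    )
    tries <- 0L
    while (sum(field > 0) < k && tries < 5L) {  # not enough structure: add more
      tries <- tries + 1L
      field <- field + streak_soft_field(d, spec$target_fraction, spec$streak_radius_vox)
    }
    if (sum(field > 0) < k) {
      stop(errorCondition(
        "collagen phantom: target fraction unreachable with this geometry",
        class = c("myomap_generation_error", "error")
      ))
    }
    ord <- order(field, decreasing = TRUE)  # deterministic tie-break by index
    m <- logical(V)
    m[ord[seq_len(k)]] <- TRUE
    array(m, d)
  })
  list(
    mask = volume3d(mask * 1, intensity_kind = "binary_mask"),
    achieved_fraction = sum(mask) / V
  )
}
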