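#' Fit a local ventricular-wall coordinate frame to a tissue slab
#'
#' Builds the per-voxel orthonormal right-handed triad (circumferential `c`,
#' longitudinal `l`, radial/transmural `r`, with `c x l = r`) and a
#' normalised transmural depth in `[0, 1]` (0 = epicardium, 1 = endocardium)
#' against which helical and intrusion angles are measured.
#'
#' In `"slab_axes"` mode (default, appropriate for transmural tissue blocks
#' cut roughly parallel to the wall) `r` is a designated lattice axis
#' pointing from the epicardial face (low index) to the endocardial face,
#' `l` is a second designated axis, and `c = l x r`. Depth is computed per
#' transmural column between the first and last tissue voxel, so warped slab
#' surfaces do not bias depth binning.
#'
#' In `"surface_normal"` mode, for curved samples, `r` is the normalised
#' gradient of the Euclidean distance to a labelled epicardial surface,
#' depth is `d_epi / (d_epi + d_endo)`, `l` is the projection of a global
#' long-axis hint onto the plane perpendicular to `r`, and `c` completes the
#' triad.
#'
#' @param tissue_mask a binary [volume3d] marking tissue voxels.
#' @param mode `"slab_axes"` or `"surface_normal"`.
#' @param radial_axis,longitudinal_axis lattice axes (1 = depth, 2 = row,
#'   3 = col) used in slab mode.
#' @param epi_mask,endo_mask binary [volume3d]s labelling the epicardial and
#'   endocardial faces (required in `surface_normal` mode).
#' @param long_axis_hint global long-axis direction hint for
#'   `surface_normal` mode.
#' @return A `wall_frame`: unit-vector fields or constant vectors `c_vec`,
#'   `l_vec`, `r_vec`, a `depth` array (NA outside tissue), the tissue mask
#'   and the mode.
#' @export
fit_wall_frame <- function(tissue_mask, mode = c("slab_axes", "surface_normal"),
                           radial_axis = 1L, longitudinal_axis = 2L,
                           epi_mask = NULL, endo_mask = NULL,
                           long_axis_hint = NULL) {
  mode <- match.arg(mode)
  stopifnot(is_volume3d(tissue_mask))
  m <- tissue_mask$data != 0
  if (!any(m)) stop_validation("fit_wall_frame: tissue mask is empty")
  d <- dim(m)

  if (mode == "slab_axes") {
    radial_axis <- as.integer(radial_axis)
    longitudinal_axis <- as.integer(longitudinal_axis)
    if (radial_axis == longitudinal_axis ||
        !all(c(radial_axis, longitudinal_axis) %in% 1:3)) {
      stop_validation("radial_axis and longitudinal_axis must be distinct axes in 1:3")
    }
    e <- diag(3)
    r_vec <- e[radial_axis, ]
    l_vec <- e[longitudinal_axis, ]
    c_vec <- cross3(l_vec, r_vec)  # then c x l = r

    # per-column depth along the radial axis between first/last tissue voxel
    perm <- c(radial_axis, setdiff(1:3, radial_axis))
    mp <- aperm(m, perm)
    na <- dim(mp)[1]
    ncol2 <- prod(dim(mp)[2:3])
    mm <- matrix(mp, nrow = na)
    idx <- seq_len(na)
    first <- apply(mm, 2L, function(v) if (any(v)) which.max(v) else NA_integer_)
    last <- na + 1L - apply(mm[rev(idx), , drop = FALSE], 2L,
                            function(v) if (any(v)) which.max(v) else NA_integer_)
    span <- pmax(last - first, 1L)
    depth_col <- (matrix(rep(idx, ncol2), nrow = na) -
                    matrix(first, na, ncol2, byrow = TRUE)) /
      matrix(span, na, ncol2, byrow = TRUE)
    depth_col <- pmin(pmax(depth_col, 0), 1)
    dp <- array(depth_col, dim(mp))
    dp[!mp] <- NA_real_
    depth <- aperm(dp, order(perm))
  } else {
    if (is.null(epi_mask) || is.null(endo_mask)) {
      stop_validation("surface_normal mode requires labelled epi_mask and endo_mask")
    }
    stopifnot(is_volume3d(epi_mask), is_volume3d(endo_mask))
    if (!any(epi_mask$data != 0) || !any(endo_mask$data != 0)) {
      stop_validation("surface_normal mode requires non-empty epi/endo face labels")
    }
    long_axis_hint <- long_axis_hint %||% c(0, 1, 0)
    d_epi <- sqrt(cpp_edt3(epi_mask$data != 0, d))
    d_endo <- sqrt(cpp_edt3(endo_mask$data != 0, d))
    depth <- d_epi / pmax(d_epi + d_endo, .Machine$double.eps)
    depth[!m] <- NA_real_

    # r = normalised gradient of the transmural signed-distance-like field
    # d_epi - d_endo (same normal as grad d_epi for parallel surfaces, but
    # much less sensitive to surface voxelisation), smoothed at sigma = 2
    sm <- cpp_sep_conv3(d_epi - d_endo, d, lapply(c(2, 2, 2), gaussian_kernel))
    g1 <- (shift_clamped(sm, 1L, 1L) - shift_clamped(sm, 1L, -1L)) / 2
    g2 <- (shift_clamped(sm, 2L, 1L) - shift_clamped(sm, 2L, -1L)) / 2
    g3 <- (shift_clamped(sm, 3L, 1L) - shift_clamped(sm, 3L, -1L)) / 2
    gn <- sqrt(g1^2 + g2^2 + g3^2)
    ok <- gn > 1e-12
    g1[ok] <- g1[ok] / gn[ok]; g2[ok] <- g2[ok] / gn[ok]; g3[ok] <- g3[ok] / gn[ok]
    g1[!ok] <- 1; g2[!ok] <- 0; g3[!ok] <- 0
    r_field <- array(c(g1, g2, g3), c(d, 3L))

    h <- long_axis_hint / sqrt(sum(long_axis_hint^2))
    hr <- g1 * h[1] + g2 * h[2] + g3 * h[3]
    l1 <- h[1] - hr * g1; l2 <- h[2] - hr * g2; l3 <- h[3] - hr * g3
    ln <- sqrt(l1^2 + l2^2 + l3^2)
    bad <- ln <= 1e-8
    if (any(bad)) {  # hint parallel to r: fall back to another axis
      alt <- c(0, 0, 1)
      ar <- g1 * alt[1] + g2 * alt[2] + g3 * alt[3]
      l1[bad] <- (alt[1] - ar * g1)[bad]
      l2[bad] <- (alt[2] - ar * g2)[bad]
      l3[bad] <- (alt[3] - ar * g3)[bad]
      ln <- sqrt(l1^2 + l2^2 + l3^2)
    }
    l1 <- l1 / ln; l2 <- l2 / ln; l3 <- l3 / ln
    l_field <- array(c(l1, l2, l3), c(d, 3L))
    # c = l x r so that c x l = r
    c1 <- l2 * g3 - l3 * g2
    c2 <- l3 * g1 - l1 * g3
    c3 <- l1 * g2 - l2 * g1
    c_field <- array(c(c1, c2, c3), c(d, 3L))
    r_vec <- r_field; l_vec <- l_field; c_vec <- c_field
  }

  structure(
    list(c_vec = c_vec, l_vec = l_vec, r_vec = r_vec, depth = depth,
         mask = m, mode = mode,
         per_voxel = mode == "surface_normal",
         voxel_size_um = tissue_mask$voxel_size_um),
    class = "wall_frame"
  )
}

# Dot product of an orientation field (dims x 3) with a frame basis vector
# that is either a constant 3-vector or a per-voxel (dims x 3) field.
frame_dot <- function(v, basis) {
  d3 <- dim(v)
  n <- prod(d3[1:3])
  vm <- matrix(v, ncol = 3L)
  if (is.null(dim(basis)) || length(basis) == 3L) {
    out <- vm[, 1] * basis[1] + vm[, 2] * basis[2] + vm[, 3] * basis[3]
  } else {
    bm <- matrix(basis, ncol = 3L)
    out <- rowSums(vm * bm)
  }
  array(out, d3[1:3])
}

check_same_lattice <- function(fibers, frame) {
  if (!identical(dim(fibers$v)[1:3], dim(frame$depth))) {
    stop_validation("orientation field and wall frame are on different lattices")
  }
}

# Sign-normalise axial fiber vectors so v.c >= 0; ties broken by v.l >= 0,
# then v.r >= 0. Returns the three frame components of the normalised field.
signed_frame_components <- function(fibers, frame) {
  vc <- frame_dot(fibers$v, frame$c_vec)
  vl <- frame_dot(fibers$v, frame$l_vec)
  vr <- frame_dot(fibers$v, frame$r_vec)
  s <- sign(vc)
  tie <- s == 0
  s[tie] <- sign(vl)[tie]
  tie <- s == 0
  s[tie] <- sign(vr)[tie]
  s[s == 0] <- 1
  list(vc = vc * s, vl = vl * s, vr = vr * s)
}

#' Helical angle of fiber directions in a wall frame
#'
#' The helical angle (HA) is the angle between the circumferential
#' direction and the fiber direction projected onto the wall-tangent
#' (circumferential-longitudinal) plane: `HA = atan2(v.l, v.c)` after axial
#' sign normalisation (`v.c >= 0`), in degrees in `(-90, 90]`. Healthy
#' myocardium classically ramps from about +60 deg at the sub-epicardium to
#' about -60 deg at the sub-endocardium. Voxels whose fiber is essentially
#' radial (tangential component below 1e-6) have no defined HA and are NA.
#'
#' @param fibers an `orientation_field`.
#' @param frame a `wall_frame` on the same lattice.
#' @return 3D array of HA in degrees; NA where invalid.
#' @export
helical_angle <- function(fibers, frame) {
  stopifnot(inherits(fibers, "orientation_field"), inherits(frame, "wall_frame"))
  check_same_lattice(fibers, frame)
  fc <- signed_frame_components(fibers, frame)
  ha <- atan2(fc$vl, fc$vc) * 180 / pi
  ha[ha <= -90] <- ha[ha <= -90] + 180  # fold onto (-90, 90]
  tang <- sqrt(fc$vc^2 + fc$vl^2)
  ha[tang < 1e-6] <- NA_real_
  ha[!fibers$valid] <- NA_real_
  ha
}

#' Intrusion angle of fiber directions in a wall frame
#'
#' The intrusion angle (IA, also transverse angle) measures how far the
#' fiber tilts out of the wall-tangent plane toward the radial direction.
#' The default `"elevation"` convention reports
#' `IA = asin(v.r)` (degrees, `[-90, 90]`): 0 for in-plane fibers, +/-90 for
#' purely radial fibers, matching the reading that disorganised trabecular
#' tissue shows *higher* IA. The `"to_radial"` convention reports the
#' literal angle to the radial direction, `90 - |elevation|`.
#'
#' @inheritParams helical_angle
#' @param convention `"elevation"` (default) or `"to_radial"`.
#' @return 3D array of IA in degrees; NA where invalid.
#' @export
intrusion_angle <- function(fibers, frame, convention = c("elevation", "to_radial")) {
  convention <- match.arg(convention)
  stopifnot(inherits(fibers, "orientation_field"), inherits(frame, "wall_frame"))
  check_same_lattice(fibers, frame)
  fc <- signed_frame_components(fibers, frame)
  ia <- asin(pmin(pmax(fc$vr, -1), 1)) * 180 / pi
  if (convention == "to_radial") ia <- 90 - abs(ia)
  ia[!fibers$valid] <- NA_real_
  ia
}

#' Transmural profile of an angle field
#'
#' Bins valid voxels by normalised transmural depth into `n_bins`
#' equal-width bins and computes the per-bin axial mean and dispersion with
#' angle-doubling circular statistics (orientations are sign-free, so plain
#' averaging would be wrong near +/-90 deg). Bins with no valid voxels are
#' marked `empty` rather than reported as zero.
#'
#' @param angle_field 3D array of angles in degrees (NA = invalid), e.g.
#'   from [helical_angle()] or [intrusion_angle()].
#' @param frame a `wall_frame` providing the depth coordinate.
#' @param n_bins number of depth bins (>= 2; use [axial_mean_angle()] for a
#'   single global summary).
#' @param mask optional additional logical mask of voxels to include.
#' @return A `data.frame` of class `transmural_profile` with columns
#'   `bin_center`, `mean_angle_deg`, `dispersion_deg`, `n`, `empty`.
#' @export
transmural_profile <- function(angle_field, frame, n_bins = 20L, mask = NULL) {
  stopifnot(inherits(frame, "wall_frame"))
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop_validation("n_bins must be >= 1")
  ok <- is.finite(angle_field) & is.finite(frame$depth)
  if (!is.null(mask)) ok <- ok & mask
  if (!any(ok)) stop_validation("transmural_profile: no valid voxels")
  depth <- frame$depth[ok]
  theta <- angle_field[ok]
  bin <- pmin(pmax(floor(depth * n_bins), 0), n_bins - 1L) + 1L
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  mean_a <- rep(NA_real_, n_bins)
  disp <- rep(NA_real_, n_bins)
  n <- tabulate(bin, nbins = n_bins)
  for (b in which(n > 0L)) {
    th <- theta[bin == b]
    mean_a[b] <- axial_mean(th)
    disp[b] <- axial_dispersion(th)
  }
  out <- data.frame(
    bin_center = centers, mean_angle_deg = mean_a,
    dispersion_deg = disp, n = n, empty = n == 0L
  )
  class(out) <- c("transmural_profile", "data.frame")
  out
}

#' Axial (orientation) mean of an angle field
#'
#' Angle-doubling mean over all finite voxels; the `n_bins = 1` limit of
#' [transmural_profile()].
#'
#' @param angle_field 3D array of angles in degrees (NA ignored).
#' @return mean angle in degrees.
#' @export
axial_mean_angle <- function(angle_field) {
  th <- angle_field[is.finite(angle_field)]
  if (!length(th)) stop_validation("no valid angles")
  axial_mean(th)
}

#' Mean fractional anisotropy over a region
#'
#' Arithmetic mean of FA over the valid voxels of a region of interest —
#' the "mean FA in selected area" summary statistic for a sample.
#'
#' @param fa_field 3D array of FA values (e.g. [fractional_anisotropy()]).
#' @param region an [roi_box], a logical array, or `NULL` for the whole
#'   lattice.
#' @param valid optional logical array of valid voxels (e.g. `map$valid`).
#' @return the mean FA (scalar) with attribute `n_voxels`, the count of
#'   contributing voxels.
#' @export
mean_fa <- function(fa_field, region = NULL, valid = NULL) {
  sel <- array(TRUE, dim(fa_field))
  if (inherits(region, "roi_box")) {
    check_roi_in_dim(region, dim(fa_field))
    tmp <- array(FALSE, dim(fa_field))
    ix <- roi_index(region)
    tmp[ix[[1]], ix[[2]], ix[[3]]] <- TRUE
    sel <- tmp
  } else if (!is.null(region)) {
    if (is_volume3d(region)) region <- region$data != 0
    sel <- sel & region
  }
  if (!is.null(valid)) sel <- sel & valid
  sel <- sel & is.finite(fa_field)
  n <- sum(sel)
  if (n == 0L) stop_validation("mean_fa: region contains no valid voxels")
  structure(mean(fa_field[sel]), n_voxels = n)
}

#' Otsu threshold of a numeric array
#'
#' Histogram-based between-class variance maximisation, used for the default
#' tissue mask (threshold on the smoothed volume, then largest connected
#' component).
#'
#' @param x numeric array or vector.
#' @param n_breaks number of histogram bins.
#' @return threshold value; voxels `> threshold` are foreground.
#' @export
otsu_threshold <- function(x, n_breaks = 256L) {
  v <- as.numeric(x[is.finite(x)])
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_breaks + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = n_breaks)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_breaks]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# Default tissue mask: Otsu on the pre-smoothed volume, then the largest
# 6-connected foreground component.
default_tissue_mask <- function(vol, sigma_vox = 2) {
  sm <- cpp_sep_conv3(vol$data, dim(vol$data), lapply(rep(sigma_vox, 3), gaussian_kernel))
  thr <- otsu_threshold(sm)
  fg <- sm > thr
  if (!any(fg)) fg <- array(TRUE, dim(vol$data))
  cpp_largest_component(fg, dim(vol$data))
}

#' Full myomapping pipeline: volume to HA/IA/FA maps
#'
#' Runs structure tensor -> eigendecomposition -> fiber directions ->
#' helical/intrusion angles and fractional anisotropy against a wall frame,
#' and assembles the co-registered `myo_map`. Validity requires tissue, a
#' non-degenerate tensor, and (by default) at least one integration-window
#' width of distance from the lattice boundary, where replicated-edge
#' smoothing biases orientations.
#'
#' @param vol a grayscale [volume3d].
#' @param frame a `wall_frame`, or `NULL` to fit a slab frame from the
#'   tissue mask with `radial_axis = 1`.
#' @param tissue_mask binary [volume3d] or logical array; `NULL` uses an
#'   Otsu + largest-component default; `"all"` uses the full lattice.
#' @param window_size_um,gradient_scale_um,window_kind see
#'   [compute_structure_tensor()].
#' @param eps degeneracy threshold, see [eigendecompose_field()].
#' @param ia_convention see [intrusion_angle()].
#' @param exclude_margin drop one window width at each lattice boundary from
#'   the valid set (default `TRUE`).
#' @return A `myo_map`: arrays `HA`, `IA`, `FA` (NA/sentinel outside
#'   `valid`), logical `valid`, the `frame`, the `fibers` and metadata.
#' @export
compute_myomap <- function(vol, frame = NULL, tissue_mask = NULL,
                           window_size_um = 123.5, gradient_scale_um = NULL,
                           window_kind = "fwhm", eps = 1e-6,
                           ia_convention = "elevation", exclude_margin = TRUE) {
  stopifnot(is_volume3d(vol))
  d <- dim(vol$data)
  tm <- if (is.null(tissue_mask)) {
    default_tissue_mask(vol)
  } else if (identical(tissue_mask, "all")) {
    array(TRUE, d)
  } else if (is_volume3d(tissue_mask)) {
    tissue_mask$data != 0
  } else {
    tissue_mask != 0
  }
  if (is.null(frame)) {
    frame <- fit_wall_frame(volume3d((tm) * 1, vol$voxel_size_um, "binary_mask"))
  }
  tf <- compute_structure_tensor(vol, window_size_um = window_size_um,
                                 gradient_scale_um = gradient_scale_um,
                                 window_kind = window_kind)
  eig <- eigendecompose_field(tf, eps = eps)
  fa <- fractional_anisotropy(eig)
  fibers <- fiber_directions(eig)
  ha <- helical_angle(fibers, frame)
  ia <- intrusion_angle(fibers, frame, convention = ia_convention)

  valid <- tm & fibers$valid & is.finite(frame$depth)
  if (exclude_margin) {
    mg <- tf$margin_vox
    interior <- array(FALSE, d)
    if (all(d > 2 * mg)) {
      interior[(mg[1] + 1):(d[1] - mg[1]),
               (mg[2] + 1):(d[2] - mg[2]),
               (mg[3] + 1):(d[3] - mg[3])] <- TRUE
    } else {
      warning("volume too small to exclude a full window margin; keeping all voxels")
      interior[] <- TRUE
    }
    valid <- valid & interior
  }
  ha[!valid] <- NA_real_
  ia[!valid] <- NA_real_
  structure(
    list(HA = ha, IA = ia, FA = fa, valid = valid, frame = frame,
         fibers = fibers, voxel_size_um = vol$voxel_size_um,
         window_size_um = window_size_um, ia_convention = ia_convention),
    class = "myo_map"
  )
}

#' @export
print.myo_map <- function(x, ...) {
  d <- dim(x$FA)
  cat(sprintf(
    "<myo_map> %d x %d x %d voxels, %d valid (%.1f%%)\n  window %g um, IA convention '%s'\n  mean FA (valid): %.4f\n",
    d[1], d[2], d[3], sum(x$valid), 100 * mean(x$valid),
    x$window_size_um, x$ia_convention, mean(x$FA[x$valid])
  ))
  invisible(x)
}
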