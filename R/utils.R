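#' @useDynLib myomap3d, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif
#' @importFrom utils write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers can distinguish bad user input from bad files.
stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("myomap_validation_error", "error")))
}
stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("myomap_input_error", "error")))
}
stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("myomap_format_error", "error")))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Normalised Gaussian kernel with the given sigma in voxels; numeric(0)
# means "skip this axis" (used when sigma is effectively zero).
gaussian_kernel <- function(sigma_vox) {
  if (sigma_vox <= 1e-8) return(numeric(0))
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# Box kernel of the given full width in voxels (odd-rounded).
box_kernel <- function(width_vox) {
  w <- max(1L, as.integer(round(width_vox)))
  if (w %% 2L == 0L) w <- w + 1L
  if (w == 1L) return(numeric(0))
  rep(1 / w, w)
}

# Shift a 3D array along an axis with edge replication (clamped indices).
shift_clamped <- function(x, axis, by) {
  d <- dim(x)
  idx <- pmin(pmax(seq_len(d[axis]) + by, 1L), d[axis])
  switch(axis, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE], x[, , idx, drop = FALSE])
}

# Axial (orientation) difference between two angle fields in degrees,
# folded into [0, 90].
axial_angle_diff <- function(a, b) {
  d <- abs(((a - b + 90) %% 180) - 90)
  d
}

# Axial mean and dispersion of angles in degrees via angle doubling.
axial_mean <- function(theta_deg) {
  t2 <- 2 * theta_deg * pi / 180
  m2 <- atan2(sum(sin(t2)), sum(cos(t2)))
  (m2 / 2) * 180 / pi
}
axial_dispersion <- function(theta_deg) {
  t2 <- 2 * theta_deg * pi / 180
  rbar <- sqrt(mean(sin(t2))^2 + mean(cos(t2))^2)
  rbar <- min(max(rbar, 1e-300), 1)
  (sqrt(-2 * log(rbar)) / 2) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vlog <- function(verbose, ...) if (isTRUE(verbose)) message(...)
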