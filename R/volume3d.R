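#' 3D scalar volume with voxel-size metadata
#'
#' The basic container for a reconstructed tomographic scan or a binary
#' segmentation mask: a 3D numeric lattice in `(depth, row, col)` axis order
#' together with the physical voxel size in micrometres per axis.
#'
#' @param data 3D numeric array, dimensions `(depth, row, col)`, all >= 1.
#' @param voxel_size_um length-3 positive numeric, micrometres per voxel along
#'   each axis. A scalar is recycled to all three axes.
#' @param intensity_kind `"grayscale"` or `"binary_mask"`. Binary masks must
#'   contain only the values 0 and 1.
#' @return An object of class `volume3d` with fields `data`, `voxel_size_um`
#'   and `intensity_kind`.
#' @examples
#' v <- volume3d(array(runif(8 * 8 * 8), c(8, 8, 8)), voxel_size_um = 5.8)
#' dim(v$data)
#' @export
volume3d <- function(data, voxel_size_um = c(1, 1, 1),
                     intensity_kind = c("grayscale", "binary_mask")) {
  intensity_kind <- match.arg(intensity_kind)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_validation("volume3d: `data` must be a 3D array")
  }
  if (any(dim(data) < 1L)) stop_validation("volume3d: all dimensions must be >= 1")
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0)) {
    stop_validation("volume3d: voxel sizes must be three strictly positive reals")
  }
  storage.mode(data) <- "double"
  if (intensity_kind == "binary_mask" && !all(data %in% c(0, 1))) {
    stop_validation("volume3d: binary_mask volumes may contain only {0, 1}")
  }
  structure(
    list(data = data, voxel_size_um = voxel_size_um, intensity_kind = intensity_kind),
    class = "volume3d"
  )
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume3d> %d x %d x %d voxels (depth x row x col), %s\n  voxel size: %g x %g x %g um\n  intensity range: [%g, %g]\n",
    d[1], d[2], d[3], x$intensity_kind,
    x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3],
    min(x$data), max(x$data)
  ))
  invisible(x)
}

is_volume3d <- function(x) inherits(x, "volume3d")

as_volume3d <- function(x, voxel_size_um = c(1, 1, 1), intensity_kind = "grayscale") {
  if (is_volume3d(x)) x else volume3d(x, voxel_size_um, intensity_kind)
}

#' Rectangular region of interest (0-based, half-open)
#'
#' Defines an axis-aligned box of voxels `[lo, hi)` per axis, using 0-based
#' indices as is conventional in imaging toolchains. A box with
#' `lo = c(0,0,0)` and `hi = dim` covers the whole volume.
#'
#' @param lo integer triple, inclusive lower corner (0-based).
#' @param hi integer triple, exclusive upper corner; `lo[i] < hi[i]` required.
#' @param label region name, e.g. `"sub-epicardium"`.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(lo, hi, label = "roi") {
  lo <- as.integer(lo)
  hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L || anyNA(lo) || anyNA(hi)) {
    stop_validation("roi_box: lo and hi must be integer triples")
  }
  if (any(lo < 0L)) stop_validation("roi_box: lo must be >= 0 (0-based indexing)")
  if (any(lo >= hi)) stop_validation("roi_box: need lo[i] < hi[i] on every axis")
  structure(list(lo = lo, hi = hi, label = as.character(label)), class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf(
    "<roi_box> '%s' [%d,%d) x [%d,%d) x [%d,%d)  (%d voxels)\n",
    x$label, x$lo[1], x$hi[1], x$lo[2], x$hi[2], x$lo[3], x$hi[3],
    prod(x$hi - x$lo)
  ))
  invisible(x)
}

# Check the box fits inside a volume of dimension `d`; error otherwise.
check_roi_in_dim <- function(roi, d, what = "volume") {
  if (any(roi$hi > d)) {
    stop_validation(sprintf(
      "ROI '%s' exceeds %s extent (%s > %s)", roi$label, what,
      paste(roi$hi, collapse = "x"), paste(d, collapse = "x")
    ))
  }
  invisible(roi)
}

# 1-based R index ranges for an roi_box.
roi_index <- function(roi) {
  list(
    seq.int(roi$lo[1] + 1L, roi$hi[1]),
    seq.int(roi$lo[2] + 1L, roi$hi[2]),
    seq.int(roi$lo[3] + 1L, roi$hi[3])
  )
}

roi_slice <- function(arr, roi) {
  ix <- roi_index(roi)
  arr[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}
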