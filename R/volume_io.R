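#' Read a tomographic volume from a multi-page TIFF or NRRD file
#'
#' Axis convention is `(depth, row, col)`: TIFF pages map to depth slices,
#' NRRD sizes are stored fastest-axis-first (col, row, depth) as usual for
#' image NRRDs. TIFF carries no reliable physical spacing, so for TIFF the
#' voxel size must come from `voxel_size_um` (a warning is logged and
#' (1,1,1) um assumed otherwise); NRRD `spacings` are authoritative unless
#' explicitly overridden.
#'
#' @param path file ending in `.tif`/`.tiff` or `.nrrd`.
#' @param voxel_size_um optional voxel size override (scalar or triple, um).
#' @param as_mask if `TRUE` the volume is coerced to a `{0,1}` binary mask;
#'   nonzero values (e.g. 255-valued masks) become 1 with a warning.
#' @return A [volume3d].
#' @export
read_volume <- function(path, voxel_size_um = NULL, as_mask = FALSE) {
  if (!file.exists(path)) stop_input("input file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    arr <- read_tiff_stack(path)
    vs <- voxel_size_um
    if (is.null(vs)) {
      warning("TIFF stores no voxel size; assuming 1 x 1 x 1 um (pass voxel_size_um to override)")
      vs <- c(1, 1, 1)
    }
  } else if (ext == "nrrd") {
    nr <- read_nrrd(path)
    if (length(dim(nr$data)) != 3L) stop_format("expected a scalar 3D NRRD: ", path)
    arr <- nr$data
    vs <- voxel_size_um %||% nr$spacings_um
    if (is.null(vs)) {
      warning("NRRD has no spacings; assuming 1 x 1 x 1 um (pass voxel_size_um to override)")
      vs <- c(1, 1, 1)
    }
  } else {
    stop_format("unsupported volume format: .", ext, " (use .tif/.tiff or .nrrd)")
  }
  if (any(vs <= 0) || any(!is.finite(vs))) {
    stop_validation("non-positive voxel size for ", path)
  }
  kind <- "grayscale"
  if (as_mask) {
    if (any(!arr %in% c(0, 1))) {
      warning("coercing nonzero mask values to 1 in ", path)
      arr <- (arr != 0) * 1
    }
    kind <- "binary_mask"
  }
  volume3d(arr, voxel_size_um = vs, intensity_kind = kind)
}

#' Write a volume as a multi-page TIFF or NRRD file
#'
#' The format is chosen by extension. Integer-valued data round-trips
#' exactly in both formats (8/16-bit as appropriate); floating point data is
#' stored losslessly as 64-bit raw in NRRD and as 32-bit float in TIFF.
#' Binary masks are stored 8-bit `{0,1}`. NRRD records the voxel size in its
#' `spacings` field; TIFF cannot, so pair TIFF files with an explicit voxel
#' size on read.
#'
#' @param vol a [volume3d].
#' @param path destination ending in `.tif`/`.tiff` or `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume3d(vol))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_input("parent directory does not exist: ", dir)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    sample <- if (vol$intensity_kind == "binary_mask") list(bits = 8L, sfmt = 1L) else NULL
    write_tiff_stack(vol$data, path, sample = sample)
  } else if (ext == "nrrd") {
    type <- if (vol$intensity_kind == "binary_mask") "uint8" else NULL
    write_nrrd(vol$data, path, spacings_um = vol$voxel_size_um, type = type)
  } else {
    stop_format("unsupported volume format: .", ext, " (use .tif/.tiff or .nrrd)")
  }
  invisible(path)
}

#' Extract the three orthogonal planes through a voxel
#'
#' Pure lattice extraction (no resampling) of the axial, coronal and
#' sagittal planes through `index`, the 2D cuts used for virtual
#' histopathology of a reconstructed scan.
#'
#' @param vol a [volume3d].
#' @param index 0-based voxel triple `(depth, row, col)`.
#' @return A list with 2D matrices `axial` (row x col at fixed depth),
#'   `coronal` (depth x col at fixed row) and `sagittal` (depth x row at
#'   fixed col).
#' @export
orthogonal_slices <- function(vol, index = c(0L, 0L, 0L)) {
  stopifnot(is_volume3d(vol))
  index <- as.integer(index)
  d <- dim(vol$data)
  if (length(index) != 3L || any(index < 0L) || any(index >= d)) {
    stop_validation("slice index out of bounds: (", paste(index, collapse = ", "),
                    ") for volume ", paste(d, collapse = "x"))
  }
  i <- index + 1L
  list(
    axial = vol$data[i[1], , , drop = TRUE],
    coronal = vol$data[, i[2], , drop = TRUE],
    sagittal = vol$data[, , i[3], drop = TRUE]
  )
}
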