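#' Collagen volume fraction in a region of interest
#'
#' Counts collagen voxels in `roi` (intersected with `tissue_mask` when one
#' is supplied, in which case the denominator is tissue voxels only) and
#' reports the percentage. Counting is exact integer arithmetic; division
#' happens once at the end.
#'
#' @param mask binary [volume3d] collagen segmentation (1 = collagen).
#' @param roi an [roi_box] within the mask extent.
#' @param tissue_mask optional binary [volume3d] or logical array; when
#'   given, only tissue voxels enter the denominator.
#' @return list with `percent` (in `[0, 100]`), `n_collagen`, `n_voxels`.
#' @export
percent_collagen <- function(mask, roi, tissue_mask = NULL) {
  stopifnot(is_volume3d(mask))
  if (mask$intensity_kind != "binary_mask" && !all(mask$data %in% c(0, 1))) {
    stop_validation("percent_collagen: mask must be binary {0,1}")
  }
  check_roi_in_dim(roi, dim(mask$data), "mask")
  sub <- roi_slice(mask$data, roi)
  if (!is.null(tissue_mask)) {
    tm <- if (is_volume3d(tissue_mask)) tissue_mask$data != 0 else tissue_mask != 0
    if (!identical(dim(tm), dim(mask$data))) {
      stop_validation("tissue_mask must match the collagen mask lattice")
    }
    tsub <- roi_slice(tm, roi)
    n_vox <- sum(tsub)
    n_col <- sum(sub[tsub] != 0)
  } else {
    n_vox <- length(sub)
    n_col <- sum(sub != 0)
  }
  if (n_vox == 0L) stop_validation("percent_collagen: empty denominator in ROI '", roi$label, "'")
  list(percent = 100 * n_col / n_vox, n_collagen = as.integer(n_col),
       n_voxels = as.integer(n_vox))
}

#' Regional collagen report (sub-epicardium / mid-myocardium / sub-endocardium)
#'
#' Computes the collagen percentage in each of three labelled transmural
#' regions and their unweighted average — the per-sample summary row set
#' of a regional fibrosis table. Percentages are carried at full precision;
#' rounding happens only at presentation ([write_collagen_csv()]).
#'
#' @param mask binary [volume3d] collagen segmentation.
#' @param rois list of three [roi_box]es with distinct labels (conventionally
#'   `"sub-epicardium"`, `"mid-myocardium"`, `"sub-endocardium"`).
#' @param tissue_mask optional, see [percent_collagen()].
#' @param sample_id sample identifier carried into the report.
#' @return A `collagen_report`: `sample_id`, `regions` data.frame
#'   (label, percent, n_voxels, n_collagen) and `average`.
#' @export
regional_collagen_report <- function(mask, rois, tissue_mask = NULL,
                                     sample_id = "sample") {
  if (!is.list(rois) || length(rois) != 3L ||
      !all(vapply(rois, inherits, logical(1), "roi_box"))) {
    stop_validation("rois must be a list of three roi_box objects")
  }
  labels <- vapply(rois, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop_validation("duplicate ROI labels: ",
                                             paste(labels, collapse = ", "))
  res <- lapply(rois, percent_collagen, mask = mask, tissue_mask = tissue_mask)
  regions <- data.frame(
    label = labels,
    percent = vapply(res, `[[`, numeric(1), "percent"),
    n_voxels = vapply(res, `[[`, integer(1), "n_voxels"),
    n_collagen = vapply(res, `[[`, integer(1), "n_collagen")
  )
  structure(
    list(sample_id = sample_id, regions = regions,
         average = mean(regions$percent)),
    class = "collagen_report"
  )
}

#' @export
print.collagen_report <- function(x, ...) {
  cat(sprintf("<collagen_report> sample '%s'\n", x$sample_id))
  for (i in seq_len(nrow(x$regions))) {
    cat(sprintf("  %-16s %6.2f%%  (%d / %d voxels)\n", x$regions$label[i],
                x$regions$percent[i], x$regions$n_collagen[i], x$regions$n_voxels[i]))
  }
  cat(sprintf("  %-16s %6.2f%%\n", "Average", x$average))
  invisible(x)
}

#' Extract a cubic sub-volume around a voxel
#'
#' Crops a physically cube-shaped sub-volume (edge length `edge_um`,
#' converted to an odd voxel count per axis) centred at `center`, e.g. a
#' mid-myocardial tissue cube exported for external 3D rendering of the
#' collagen matrix. No padding: the cube must fit inside the volume.
#'
#' @param vol a [volume3d] (grayscale volume or binary mask).
#' @param center 0-based voxel triple.
#' @param edge_um physical edge length in micrometres.
#' @return the cropped [volume3d] with inherited voxel size.
#' @export
extract_cube <- function(vol, center, edge_um) {
  stopifnot(is_volume3d(vol))
  center <- as.integer(center)
  d <- dim(vol$data)
  if (length(center) != 3L || any(center < 0L) || any(center >= d)) {
    stop_validation("cube center out of bounds")
  }
  if (!is.numeric(edge_um) || edge_um <= 0) stop_validation("edge_um must be positive")
  e_vox <- pmax(1L, as.integer(round(edge_um / vol$voxel_size_um)))
  e_vox <- e_vox + (1L - e_vox %% 2L)  # odd-rounded
  half <- (e_vox - 1L) %/% 2L
  lo <- center - half
  hi <- center + half + 1L  # half-open
  if (any(lo < 0L) || any(hi > d)) {
    stop_validation(sprintf(
      "cube of %g um (%s voxels) at (%s) exceeds volume bounds",
      edge_um, paste(e_vox, collapse = "x"), paste(center, collapse = ", ")
    ))
  }
  volume3d(vol$data[(lo[1] + 1L):hi[1], (lo[2] + 1L):hi[2], (lo[3] + 1L):hi[3], drop = FALSE],
           voxel_size_um = vol$voxel_size_um, intensity_kind = vol$intensity_kind)
}

#' Write collagen reports as a regional-table CSV
#'
#' Layout: rows are the three regions plus `Average`, one column per
#' sample; percentages rounded to two decimals at presentation.
#'
#' @param reports a `collagen_report` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_collagen_csv <- function(reports, path) {
  if (inherits(reports, "collagen_report")) reports <- list(reports)
  labels <- reports[[1]]$regions$label
  tab <- data.frame(region = c(labels, "Average"))
  for (rep_i in reports) {
    if (!identical(rep_i$regions$label, labels)) {
      stop_validation("all reports must share the same region labels")
    }
    tab[[rep_i$sample_id]] <- round(c(rep_i$regions$percent, rep_i$average), 2)
  }
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write collagen reports as JSON with raw counts
#'
#' Full-precision percentages plus the underlying voxel counts, so the
#' report recomputes exactly from its own numbers.
#'
#' @inheritParams write_collagen_csv
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_collagen_json <- function(reports, path) {
  if (inherits(reports, "collagen_report")) reports <- list(reports)
  payload <- lapply(reports, function(r) {
    list(sample_id = r$sample_id,
         regions = r$regions,
         average = r$average)
  })
  names(payload) <- vapply(reports, `[[`, character(1), "sample_id")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
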