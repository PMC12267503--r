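# NRRD reader/writer, raw encoding. Sizes/spacings are written in NRRD's
# fastest-axis-first order (col, row, depth), i.e. the reverse of this
# package's (depth, row, col) array convention, so files interoperate with
# the usual image tools. 3D scalar volumes plus an optional leading vector
# axis (for orientation fields) are supported.

NRRD_R_TYPE <- list(
  uint8  = list(what = "integer", size = 1L, signed = FALSE),
  uchar  = list(what = "integer", size = 1L, signed = FALSE),
  uint16 = list(what = "integer", size = 2L, signed = FALSE),
  int16  = list(what = "integer", size = 2L, signed = TRUE),
  int32  = list(what = "integer", size = 4L, signed = TRUE),
  int    = list(what = "integer", size = 4L, signed = TRUE),
  float  = list(what = "double", size = 4L, signed = TRUE),
  double = list(what = "double", size = 8L, signed = TRUE)
)

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD000[0-9]$", magic)) stop_format("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line) || !nzchar(line)) break
    if (startsWith(line, "#")) next
    sep <- regexpr(": ", line, fixed = TRUE)
    if (sep < 0) next
    key <- tolower(substr(line, 1L, sep - 1L))
    fields[[key]] <- substr(line, sep + 2L, nchar(line))
  }
  need <- c("type", "dimension", "sizes", "encoding")
  if (!all(need %in% names(fields))) {
    stop_format("NRRD header missing required fields in ", path)
  }
  if (tolower(fields$encoding) != "raw") {
    stop_format("only raw NRRD encoding is supported (got ", fields$encoding, ")")
  }
  ty <- NRRD_R_TYPE[[tolower(fields$type)]]
  if (is.null(ty)) stop_format("unsupported NRRD type: ", fields$type)
  sizes <- as.integer(strsplit(trimws(fields$sizes), "\\s+")[[1]])
  ndim <- as.integer(fields$dimension)
  if (length(sizes) != ndim || !ndim %in% c(3L, 4L)) {
    stop_format("NRRD must be 3D (or 4D vector field); got dimension ", ndim)
  }
  endian <- tolower(fields$endian %||% "little")
  n <- prod(sizes)
  vals <- readBin(con, ty$what, n = n, size = ty$size, signed = ty$signed,
                  endian = endian)
  if (length(vals) != n) stop_format("NRRD data truncated in ", path)

  spacings <- if (!is.null(fields$spacings)) {
    as.numeric(strsplit(trimws(fields$spacings), "\\s+")[[1]])
  } else NULL

  if (ndim == 3L) {
    arr <- aperm(array(vals, dim = sizes), c(3, 2, 1))
    sp <- if (!is.null(spacings)) rev(spacings) else NULL
  } else {
    # leading vector axis (fastest), then col, row, depth
    arr <- aperm(array(vals, dim = sizes), c(4, 3, 2, 1))
    sp <- if (!is.null(spacings)) rev(spacings)[1:3] else NULL
  }
  list(data = arr, spacings_um = sp, type = tolower(fields$type))
}

nrrd_pick_type <- function(data) {
  v <- range(data)
  if (all(data == round(data)) && v[1] >= 0 && v[2] <= 255) "uint8"
  else if (all(data == round(data)) && v[1] >= 0 && v[2] <= 65535) "uint16"
  else "double"
}

write_nrrd <- function(data, path, spacings_um = NULL, type = NULL) {
  d <- dim(data)
  ndim <- length(d)
  if (!ndim %in% c(3L, 4L)) stop_validation("write_nrrd: data must be 3D or 4D")
  type <- type %||% nrrd_pick_type(data)
  ty <- NRRD_R_TYPE[[type]]
  if (is.null(ty)) stop_format("unsupported NRRD type: ", type)

  if (ndim == 3L) {
    vals <- as.vector(aperm(data, c(3, 2, 1)))
    sizes <- rev(d)
    sp_line <- if (!is.null(spacings_um)) paste(rev(spacings_um), collapse = " ")
  } else {
    vals <- as.vector(aperm(data, c(4, 3, 2, 1)))
    sizes <- rev(d)
    sp_line <- if (!is.null(spacings_um)) paste(c("nan", rev(spacings_um)), collapse = " ")
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# generated by myomap3d",
    paste0("type: ", type),
    paste0("dimension: ", ndim),
    paste0("sizes: ", paste(sizes, collapse = " ")),
    if (!is.null(spacings_um)) paste0("spacings: ", sp_line),
    "encoding: raw",
    "endian: little",
    ""
  )
  writeLines(hdr, con, sep = "\n")
  if (ty$what == "integer") {
    if (ty$size == 1L) {
      writeBin(as.raw(vals), con)
    } else {
      writeBin(as.integer(vals), con, size = ty$size, endian = "little")
    }
  } else {
    writeBin(as.double(vals), con, size = ty$size, endian = "little")
  }
  invisible(path)
}
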