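# Minimal baseline TIFF codec: multi-page, single-sample grayscale,
# uncompressed, one-or-more strips. 8/16-bit unsigned integer and 32-bit
# float samples. This intentionally covers only what reconstructed
# tomography stacks need; no palette, tiling, compression or planar modes.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

rd_u16 <- function(raw, off, endian) {
  readBin(raw[(off + 1):(off + 2)], "integer", n = 1L, size = 2L,
          signed = FALSE, endian = endian)
}

rd_u32 <- function(raw, off, endian) {
  v <- readBin(raw[(off + 1):(off + 4)], "integer", n = 1L, size = 4L, endian = endian)
  if (v < 0) v <- v + 2^32
  v
}

# Read one IFD entry's value(s) as numeric vector.
tiff_entry_values <- function(raw, entry_off, endian) {
  type <- rd_u16(raw, entry_off + 2, endian)
  count <- rd_u32(raw, entry_off + 4, endian)
  tsize <- TIFF_TYPE_SIZE[as.character(type)]
  if (is.na(tsize)) return(NULL)
  nbytes <- tsize * count
  val_off <- if (nbytes <= 4) entry_off + 8 else rd_u32(raw, entry_off + 8, endian)
  vapply(seq_len(count) - 1L, function(i) {
    o <- val_off + i * tsize
    if (type == 3L) rd_u16(raw, o, endian)
    else if (type == 4L) rd_u32(raw, o, endian)
    else if (type == 1L) as.numeric(raw[o + 1])
    else NA_real_
  }, numeric(1))
}

# Parse a multi-page TIFF into a 3D array (depth = pages, row, col).
read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) stop_format("TIFF too short: ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big" else
    stop_format("not a TIFF (bad byte-order mark): ", path)
  if (rd_u16(raw, 2, endian) != 42L) stop_format("not a TIFF (bad magic): ", path)

  pages <- list()
  ifd_off <- rd_u32(raw, 4, endian)
  while (ifd_off != 0) {
    nent <- rd_u16(raw, ifd_off, endian)
    tags <- list()
    for (e in seq_len(nent)) {
      eo <- ifd_off + 2 + (e - 1) * 12
      tag <- rd_u16(raw, eo, endian)
      if (tag %in% c(256, 257, 258, 259, 262, 273, 277, 278, 279, 339)) {
        tags[[as.character(tag)]] <- tiff_entry_values(raw, eo, endian)
      }
    }
    w <- tags[["256"]][1]
    h <- tags[["257"]][1]
    bits <- (tags[["258"]] %||% 8)[1]
    comp <- (tags[["259"]] %||% 1)[1]
    spp <- (tags[["277"]] %||% 1)[1]
    sfmt <- (tags[["339"]] %||% 1)[1]
    if (comp != 1) stop_format("unsupported TIFF compression scheme ", comp)
    if (spp != 1) stop_format("only single-sample grayscale TIFF is supported")
    offs <- tags[["273"]]
    cnts <- tags[["279"]]
    rps <- (tags[["278"]] %||% h)[1]
    if (is.null(w) || is.null(h) || is.null(offs)) stop_format("incomplete TIFF IFD")

    bpp <- bits / 8
    vals <- numeric(w * h)
    row0 <- 0
    for (s in seq_along(offs)) {
      nrow_s <- min(rps, h - row0)
      nv <- nrow_s * w
      bytes <- raw[(offs[s] + 1):(offs[s] + nv * bpp)]
      v <- if (bits == 8 && sfmt %in% c(1, 2)) {
        as.numeric(bytes)
      } else if (bits == 16 && sfmt == 1) {
        readBin(bytes, "integer", n = nv, size = 2L, signed = FALSE, endian = endian)
      } else if (bits == 16 && sfmt == 2) {
        readBin(bytes, "integer", n = nv, size = 2L, signed = TRUE, endian = endian)
      } else if (bits == 32 && sfmt == 3) {
        readBin(bytes, "double", n = nv, size = 4L, endian = endian)
      } else if (bits == 32 && sfmt %in% c(1, 2)) {
        readBin(bytes, "integer", n = nv, size = 4L, endian = endian)
      } else {
        stop_format("unsupported TIFF sample: ", bits, "-bit, format ", sfmt)
      }
      vals[(row0 * w + 1):(row0 * w + nv)] <- v
      row0 <- row0 + nrow_s
    }
    # vals is row-major (col fastest); convert to an R (row, col) matrix
    pages[[length(pages) + 1L]] <- t(matrix(vals, nrow = w, ncol = h))
    ifd_off <- rd_u32(raw, ifd_off + 2 + nent * 12, endian)
  }
  if (!length(pages)) stop_format("TIFF contains no images: ", path)
  shp <- vapply(pages, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1])) {
    stop_format("inconsistent slice shapes across TIFF pages in ", path)
  }
  arr <- array(0, c(length(pages), shp[1, 1], shp[2, 1]))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  arr
}

# Pick the narrowest sample type that represents the data exactly;
# falls back to float32 (with precision loss for non-float doubles).
tiff_pick_type <- function(data) {
  v <- range(data)
  if (all(data == round(data)) && v[1] >= 0 && v[2] <= 255) {
    list(bits = 8L, sfmt = 1L)
  } else if (all(data == round(data)) && v[1] >= 0 && v[2] <= 65535) {
    list(bits = 16L, sfmt = 1L)
  } else {
    list(bits = 32L, sfmt = 3L)
  }
}

wr_entry <- function(con, tag, type, count, value) {
  writeBin(as.integer(tag), con, size = 2L, endian = "little")
  writeBin(as.integer(type), con, size = 2L, endian = "little")
  writeBin(as.integer(count), con, size = 4L, endian = "little")
  if (type == 3L) {  # SHORT, left-justified in the 4-byte field
    writeBin(as.integer(value), con, size = 2L, endian = "little")
    writeBin(0L, con, size = 2L, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4L, endian = "little")
  }
}

# Write a 3D array as a little-endian multi-page grayscale TIFF,
# one page per depth slice, one strip per page.
write_tiff_stack <- function(data, path, sample = NULL) {
  d <- dim(data)
  nz <- d[1]; h <- d[2]; w <- d[3]
  ty <- sample %||% tiff_pick_type(data)
  bpp <- ty$bits / 8
  strip_bytes <- w * h * bpp
  pad <- strip_bytes %% 2L  # keep IFDs word-aligned
  data_off <- 8 + (seq_len(nz) - 1) * (strip_bytes + pad)
  ifd_bytes <- 2 + 10 * 12 + 4
  ifd_off <- 8 + nz * (strip_bytes + pad) + (seq_len(nz) - 1) * ifd_bytes

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2L, endian = "little")
  writeBin(as.integer(ifd_off[1]), con, size = 4L, endian = "little")
  for (z in seq_len(nz)) {
    vals <- as.vector(t(data[z, , ]))  # row-major, col fastest
    if (ty$bits == 8L) {
      writeBin(as.raw(vals), con)
    } else if (ty$bits == 16L) {
      writeBin(as.integer(vals), con, size = 2L, endian = "little")
    } else {
      writeBin(as.double(vals), con, size = 4L, endian = "little")
    }
    if (pad) writeBin(as.raw(0L), con)
  }
  for (z in seq_len(nz)) {
    writeBin(10L, con, size = 2L, endian = "little")
    wr_entry(con, 256, 4L, 1L, w)
    wr_entry(con, 257, 4L, 1L, h)
    wr_entry(con, 258, 3L, 1L, ty$bits)
    wr_entry(con, 259, 3L, 1L, 1L)           # no compression
    wr_entry(con, 262, 3L, 1L, 1L)           # black-is-zero
    wr_entry(con, 273, 4L, 1L, data_off[z])
    wr_entry(con, 277, 3L, 1L, 1L)
    wr_entry(con, 278, 4L, 1L, h)
    wr_entry(con, 279, 4L, 1L, strip_bytes)
    wr_entry(con, 339, 3L, 1L, ty$sfmt)
    next_off <- if (z < nz) ifd_off[z + 1] else 0L
    writeBin(as.integer(next_off), con, size = 4L, endian = "little")
  }
  invisible(path)
}
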