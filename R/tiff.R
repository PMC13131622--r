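# Minimal baseline TIFF support for single-channel volumetric stacks.
#
# Scope is deliberately narrow: uncompressed, single-sample-per-pixel,
# striped, grayscale multi-page TIFF (the de-facto interchange format for
# microscopy z-stacks). The writer emits little-endian 32-bit float (data)
# or unsigned 8/16-bit integer (masks); the reader additionally accepts
# big-endian files. Voxel spacing round-trips through a small JSON payload
# in the ImageDescription tag (the convention used by several stack writers).
# Anything fancier (compression, tiles, RGB) is rejected with a clear error.

TIFF_TYPE_SIZES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                     `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `11` = 4L, `12` = 8L)

read_uint <- function(raw, offset, size, endian) {
  b <- as.integer(raw[(offset + 1):(offset + size)])
  if (endian == "big") b <- rev(b)
  sum(b * 256^(seq_len(size) - 1))
}

# Parse one IFD entry's values as numerics (or a character for ASCII).
tiff_entry_values <- function(raw, entry_off, endian) {
  tag <- read_uint(raw, entry_off, 2, endian)
  type <- read_uint(raw, entry_off + 2, 2, endian)
  count <- read_uint(raw, entry_off + 4, 4, endian)
  tsize <- TIFF_TYPE_SIZES[as.character(type)]
  if (is.na(tsize)) return(list(tag = tag, values = NULL))
  nbytes <- tsize * count
  data_off <- if (nbytes <= 4) entry_off + 8 else read_uint(raw, entry_off + 8, 4, endian)
  vals <- if (type == 2) {
    bytes <- raw[(data_off + 1):(data_off + count)]
    rawToChar(bytes[bytes != as.raw(0)])
  } else if (type == 11) {
    readBin(raw[(data_off + 1):(data_off + nbytes)], "double", n = count,
            size = 4, endian = endian)
  } else {
    vapply(seq_len(count) - 1L,
           function(i) read_uint(raw, data_off + i * tsize, tsize, endian),
           numeric(1))
  }
  list(tag = tag, values = vals)
}

read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  magic <- rawToChar(raw[1:2])
  endian <- switch(magic, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path))
  if (read_uint(raw, 2, 2, endian) != 42) stop("not a TIFF file: ", path)
  ifd_off <- read_uint(raw, 4, 4, endian)

  pages <- list()
  description <- NULL
  while (ifd_off != 0) {
    n_entries <- read_uint(raw, ifd_off, 2, endian)
    tags <- list()
    for (i in seq_len(n_entries)) {
      e <- tiff_entry_values(raw, ifd_off + 2 + (i - 1) * 12, endian)
      tags[[as.character(e$tag)]] <- e$values
    }
    width <- tags[["256"]][1]
    height <- tags[["257"]][1]
    bits <- (tags[["258"]] %||% 1)[1]
    compression <- (tags[["259"]] %||% 1)[1]
    spp <- (tags[["277"]] %||% 1)[1]
    fmt <- (tags[["339"]] %||% 1)[1]
    if (is.null(width) || is.null(height)) stop("TIFF page missing dimensions: ", path)
    if (compression != 1) stop("only uncompressed TIFF is supported (compression tag = ", compression, ")")
    if (spp != 1) stop("only single-channel (1 sample/pixel) TIFF is supported")
    if (!is.null(tags[["322"]])) stop("tiled TIFF is not supported")
    if (is.null(description) && !is.null(tags[["270"]])) description <- tags[["270"]]

    offsets <- tags[["273"]]
    counts <- tags[["279"]]
    if (is.null(offsets) || is.null(counts)) stop("TIFF page missing strip layout: ", path)
    payload <- raw(0)
    for (s in seq_along(offsets)) {
      payload <- c(payload, raw[(offsets[s] + 1):(offsets[s] + counts[s])])
    }
    n_px <- width * height
    vals <- if (fmt == 3) {
      if (bits != 32) stop("unsupported float bit depth: ", bits)
      readBin(payload, "double", n = n_px, size = 4, endian = endian)
    } else if (bits == 8) {
      as.numeric(readBin(payload, "integer", n = n_px, size = 1, signed = FALSE, endian = endian))
    } else if (bits == 16) {
      as.numeric(readBin(payload, "integer", n = n_px, size = 2, signed = FALSE, endian = endian))
    } else if (bits == 32) {
      as.numeric(readBin(payload, "integer", n = n_px, size = 4, endian = endian))
    } else {
      stop("unsupported bit depth: ", bits)
    }
    pages[[length(pages) + 1L]] <- list(width = width, height = height, vals = vals)
    ifd_off <- read_uint(raw, ifd_off + 2 + n_entries * 12, 4, endian)
  }
  if (length(pages) == 0) stop("TIFF contains no images: ", path)
  w <- pages[[1]]$width; h <- pages[[1]]$height
  if (!all(vapply(pages, function(p) p$width == w && p$height == h, logical(1)))) {
    stop("TIFF pages have inconsistent dimensions: ", path)
  }
  arr <- array(0, dim = c(length(pages), h, w))
  for (z in seq_along(pages)) {
    arr[z, , ] <- t(matrix(pages[[z]]$vals, nrow = w, ncol = h))
  }
  list(data = arr, description = description)
}

write_uint <- function(con, x, size) {
  # writeBin writes signed ints; sizes used here stay within signed range
  writeBin(as.integer(x), con, size = size, endian = "little")
}

# entry value packed into the 4-byte slot (value_raw must already be padded)
tiff_entry_raw <- function(tag, type, count, value_raw) {
  stopifnot(length(value_raw) == 4)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  write_uint(con, tag, 2); write_uint(con, type, 2); write_uint(con, count, 4)
  writeBin(value_raw, con)
  rawConnectionValue(con)
}

pack_short <- function(x) c(writeBin(as.integer(x), raw(), size = 2, endian = "little"), as.raw(c(0, 0)))
pack_long <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

write_tiff_stack <- function(arr, path, sample_format = c("float", "uint16", "uint8"),
                             description = NULL) {
  stopifnot(length(dim(arr)) == 3)
  sample_format <- match.arg(sample_format)
  d <- dim(arr)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  bps <- switch(sample_format, float = 32L, uint16 = 16L, uint8 = 8L)
  fmt <- if (sample_format == "float") 3L else 1L
  bytes_per_px <- bps / 8L
  page_bytes <- ny * nx * bytes_per_px

  desc_raw <- if (!is.null(description)) c(charToRaw(description), as.raw(0)) else NULL
  header_bytes <- 8L
  data0 <- header_bytes
  desc_off <- data0 + nz * page_bytes
  desc_len <- length(desc_raw)
  ifd0 <- desc_off + desc_len + (desc_len %% 2L)  # word-align IFDs

  n_tags_first <- if (is.null(desc_raw)) 10L else 11L
  n_tags_rest <- 10L
  ifd_size <- function(n) 2L + n * 12L + 4L
  ifd_offsets <- numeric(nz)
  off <- ifd0
  for (z in seq_len(nz)) {
    ifd_offsets[z] <- off
    off <- off + ifd_size(if (z == 1) n_tags_first else n_tags_rest)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  write_uint(con, 42, 2)
  write_uint(con, ifd0, 4)
  # pixel data, page by page: rows are y, x fastest within a row
  for (z in seq_len(nz)) {
    vals <- as.vector(t(arr[z, , ]))  # row-major
    if (sample_format == "float") {
      writeBin(as.numeric(vals), con, size = 4, endian = "little")
    } else {
      max_val <- if (sample_format == "uint16") 65535 else 255
      iv <- as.integer(round(vals))
      if (any(iv < 0 | iv > max_val)) stop("values out of range for ", sample_format)
      writeBin(iv, con, size = bytes_per_px, endian = "little")
    }
  }
  if (!is.null(desc_raw)) {
    writeBin(desc_raw, con)
    if (desc_len %% 2L == 1L) writeBin(as.raw(0), con)
  }
  for (z in seq_len(nz)) {
    first <- z == 1L
    entries <- list(
      tiff_entry_raw(256, 4, 1, pack_long(nx)),
      tiff_entry_raw(257, 4, 1, pack_long(ny)),
      tiff_entry_raw(258, 3, 1, pack_short(bps)),
      tiff_entry_raw(259, 3, 1, pack_short(1)),
      tiff_entry_raw(262, 3, 1, pack_short(1))
    )
    if (first && !is.null(desc_raw)) {
      entries <- c(entries, list(tiff_entry_raw(270, 2, desc_len, pack_long(desc_off))))
    }
    entries <- c(entries, list(
      tiff_entry_raw(273, 4, 1, pack_long(data0 + (z - 1) * page_bytes)),
      tiff_entry_raw(277, 3, 1, pack_short(1)),
      tiff_entry_raw(278, 4, 1, pack_long(ny)),
      tiff_entry_raw(279, 4, 1, pack_long(page_bytes)),
      tiff_entry_raw(339, 3, 1, pack_short(fmt))
    ))
    write_uint(con, length(entries), 2)
    for (e in entries) writeBin(e, con)
    write_uint(con, if (z < nz) ifd_offsets[z + 1] else 0, 4)
  }
  invisible(path)
}
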