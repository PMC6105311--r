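#' @name tiff-io
#' @title Minimal baseline TIFF codec
#'
#' @description
#' No TIFF reader/writer ships with the R stack this package depends on, so a
#' deliberately minimal baseline codec lives here: little-endian or big-endian
#' input, uncompressed, single-sample grayscale, 8/16-bit unsigned integer or
#' 32-bit float samples, multi-page (one page per optical Z plane). The writer
#' always emits little-endian files with one strip per page, an ImageJ-style
#' ImageDescription carrying the voxel calibration at full precision, and
#' X/YResolution rational tags as a secondary calibration carrier.
#'
#' These two functions deal in raw pixel grids; [read_volume()] and
#' [write_volume()] add the calibration contract on top.
#' @keywords internal
NULL

.tiff_types <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L, RATIONAL = 5L)
.tiff_type_size <- c(1L, 1L, 2L, 4L, 8L)

# --- writer -----------------------------------------------------------------

.tiff_entry <- function(tag, type, count, value_raw) {
  stopifnot(length(value_raw) <= 4L)
  pad <- as.raw(rep(0L, 4L - length(value_raw)))
  c(
    writeBin(as.integer(tag), raw(), size = 2L, endian = "little"),
    writeBin(as.integer(type), raw(), size = 2L, endian = "little"),
    writeBin(as.integer(count), raw(), size = 4L, endian = "little"),
    value_raw, pad
  )
}

.raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
.raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

#' Write a multi-page grayscale TIFF
#'
#' @param pixels 3D numeric array indexed `[page, row, column]` (a matrix is
#'   treated as one page).
#' @param path output file.
#' @param spacing `(dz, dy, dx)` in micrometres, stored in the ImageDescription
#'   (full precision) and resolution tags; `NULL` writes an uncalibrated file.
#' @param type `"float32"`, `"uint16"` or `"uint8"`. Integer types are range
#'   checked and written bit-exactly.
#' @return `path`, invisibly.
#' @keywords internal
write_tiff <- function(pixels, path, spacing = NULL, type = "float32") {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(1L, dim(pixels)))
  stopifnot(length(dim(pixels)) == 3L)
  nz <- dim(pixels)[1L]; ny <- dim(pixels)[2L]; nx <- dim(pixels)[3L]
  type <- match.arg(type, c("float32", "uint16", "uint8"))
  bits <- switch(type, float32 = 32L, uint16 = 16L, uint8 = 8L)
  fmt <- if (type == "float32") 3L else 1L
  bpp <- bits %/% 8L
  if (type != "float32") {
    if (any(pixels != round(pixels)) || any(pixels < 0) ||
        any(pixels > 2^bits - 1)) {
      stop("pixel values out of range for ", type)
    }
  }

  desc <- sprintf("ImageJ=1.53t\nimages=%d\nslices=%d\nunit=micron\n", nz, nz)
  if (!is.null(spacing)) {
    stopifnot(length(spacing) == 3L, all(spacing > 0))
    desc <- paste0(desc, sprintf(
      "spacing=%s\npixel_height=%s\npixel_width=%s\n",
      format(spacing[1L], digits = 17L),
      format(spacing[2L], digits = 17L),
      format(spacing[3L], digits = 17L)
    ))
  }
  desc_raw <- c(charToRaw(desc), as.raw(0L))

  page_bytes <- ny * nx * bpp
  desc_off <- 8L
  data_off <- desc_off + length(desc_raw)
  if (data_off %% 2L == 1L) data_off <- data_off + 1L
  rat_off <- data_off + nz * page_bytes          # 2 rationals (16 bytes)
  ifd_off0 <- rat_off + 16L

  n_entries <- if (is.null(spacing)) 11L else 14L
  ifd_size <- 2L + n_entries * 12L + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(.raw_u16(42L), con)
  writeBin(.raw_u32(ifd_off0), con)
  writeBin(desc_raw, con)
  if (data_off > desc_off + length(desc_raw)) writeBin(as.raw(0L), con)

  for (z in seq_len(nz)) {
    plane <- t(pixels[z, , , drop = TRUE])          # column-major -> row-major
    v <- as.vector(plane)
    if (type == "float32") {
      writeBin(as.numeric(v), con, size = 4L, endian = "little")
    } else {
      writeBin(as.integer(v), con, size = bpp, endian = "little")
    }
  }

  if (!is.null(spacing)) {
    # pixels per micron as rationals: num / den = 1 / d
    for (d in spacing[c(3L, 2L)]) {
      writeBin(.raw_u32(10000000L), con)
      writeBin(.raw_u32(as.integer(round(d * 1e7))), con)
    }
  } else {
    writeBin(raw(16L), con)
  }

  for (z in seq_len(nz)) {
    entries <- list(
      .tiff_entry(256L, 4L, 1L, .raw_u32(nx)),
      .tiff_entry(257L, 4L, 1L, .raw_u32(ny)),
      .tiff_entry(258L, 3L, 1L, .raw_u16(bits)),
      .tiff_entry(259L, 3L, 1L, .raw_u16(1L)),
      .tiff_entry(262L, 3L, 1L, .raw_u16(1L)),
      .tiff_entry(270L, 2L, length(desc_raw), .raw_u32(desc_off)),
      .tiff_entry(273L, 4L, 1L, .raw_u32(data_off + (z - 1L) * page_bytes)),
      .tiff_entry(277L, 3L, 1L, .raw_u16(1L)),
      .tiff_entry(278L, 4L, 1L, .raw_u32(ny)),
      .tiff_entry(279L, 4L, 1L, .raw_u32(page_bytes)),
      .tiff_entry(339L, 3L, 1L, .raw_u16(fmt))
    )
    if (!is.null(spacing)) {
      entries <- c(entries, list(
        .tiff_entry(282L, 5L, 1L, .raw_u32(rat_off)),
        .tiff_entry(283L, 5L, 1L, .raw_u32(rat_off + 8L)),
        .tiff_entry(296L, 3L, 1L, .raw_u16(1L))
      ))
    }
    tags <- vapply(entries, function(e) {
      readBin(e[1:2], "integer", size = 2L, signed = FALSE, endian = "little")
    }, integer(1L))
    entries <- entries[order(tags)]
    writeBin(.raw_u16(length(entries)), con)
    for (e in entries) writeBin(e, con)
    nxt <- if (z < nz) ifd_off0 + z * ifd_size else 0L
    writeBin(.raw_u32(nxt), con)
  }
  invisible(path)
}

# --- reader -----------------------------------------------------------------

.read_ifd_value <- function(raw_all, entry, endian) {
  type <- entry$type
  count <- entry$count
  size <- .tiff_type_size[type]
  nbytes <- size * count
  if (nbytes <= 4L) {
    bytes <- entry$value_raw[seq_len(nbytes)]
  } else {
    off <- readBin(entry$value_raw, "integer", size = 4L, endian = endian)
    bytes <- raw_all[(off + 1L):(off + nbytes)]
  }
  switch(as.character(type),
    "1" = as.integer(bytes),
    "2" = rawToChar(bytes[bytes != as.raw(0L)]),
    "3" = readBin(bytes, "integer", n = count, size = 2L, signed = FALSE,
                  endian = endian),
    "4" = readBin(bytes, "integer", n = count, size = 4L, endian = endian),
    "5" = {
      v <- readBin(bytes, "integer", n = 2L * count, size = 4L, endian = endian)
      v[v < 0] <- v[v < 0] + 2^32
      v[c(TRUE, FALSE)] / v[c(FALSE, TRUE)]
    },
    stop("unsupported TIFF tag type ", type)
  )
}

#' Read a multi-page grayscale TIFF
#'
#' @param path TIFF file.
#' @return list with `pixels` (3D array `[page, row, column]`), `description`
#'   (character or `NULL`) and `resolution` (`c(xres, yres)` pixels per unit,
#'   or `NULL`).
#' @keywords internal
read_tiff <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 8L) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw_all[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  magic <- readBin(raw_all[3:4], "integer", size = 2L, endian = endian)
  if (magic != 42L) stop("not a TIFF file: ", path)
  ifd_off <- readBin(raw_all[5:8], "integer", size = 4L, endian = endian)

  pages <- list()
  description <- NULL
  resolution <- NULL
  while (ifd_off != 0L) {
    n <- readBin(raw_all[ifd_off + 1:2], "integer", size = 2L,
                 signed = FALSE, endian = endian)
    tags <- list()
    for (i in seq_len(n)) {
      base <- ifd_off + 2L + (i - 1L) * 12L
      e <- list(
        tag = readBin(raw_all[base + 1:2], "integer", size = 2L,
                      signed = FALSE, endian = endian),
        type = readBin(raw_all[base + 3:4], "integer", size = 2L,
                       signed = FALSE, endian = endian),
        count = readBin(raw_all[base + 5:8], "integer", size = 4L,
                        endian = endian),
        value_raw = raw_all[base + 9:12]
      )
      tags[[as.character(e$tag)]] <- e
    }
    val <- function(tag, default = NULL) {
      e <- tags[[as.character(tag)]]
      if (is.null(e)) return(default)
      .read_ifd_value(raw_all, e, endian)
    }
    nx <- val(256L); ny <- val(257L)
    if (is.null(nx) || is.null(ny)) stop("malformed TIFF: missing dimensions")
    bits <- val(258L, 1L)[1L]
    if (val(259L, 1L) != 1L) stop("unsupported TIFF: compressed data")
    if (val(277L, 1L) != 1L) stop("unsupported TIFF: multi-sample pixels")
    fmt <- val(339L, 1L)[1L]
    offsets <- val(273L); counts <- val(279L)
    if (is.null(offsets)) stop("malformed TIFF: no strip offsets")
    if (is.null(counts)) counts <- ny * nx * bits %/% 8L
    bytes <- unlist(lapply(seq_along(offsets), function(i) {
      raw_all[(offsets[i] + 1L):(offsets[i] + counts[i])]
    }))
    npix <- ny * nx
    v <- if (fmt == 3L && bits == 32L) {
      readBin(bytes, "double", n = npix, size = 4L, endian = endian)
    } else if (fmt %in% c(1L, 2L) && bits %in% c(8L, 16L)) {
      readBin(bytes, "integer", n = npix, size = bits %/% 8L,
              signed = FALSE, endian = endian)
    } else if (fmt %in% c(1L, 2L) && bits == 32L) {
      x <- readBin(bytes, "integer", n = npix, size = 4L, endian = endian)
      x[x < 0] <- x[x < 0] + 2^32
      x
    } else {
      stop("unsupported TIFF sample type: ", bits, "-bit, format ", fmt)
    }
    pages[[length(pages) + 1L]] <- t(matrix(v, nrow = nx, ncol = ny))
    if (is.null(description)) description <- val(270L)
    if (is.null(resolution)) {
      xr <- val(282L); yr <- val(283L)
      if (!is.null(xr) && !is.null(yr)) resolution <- c(xr, yr)
    }
    ifd_off <- readBin(
      raw_all[ifd_off + 2L + n * 12L + 1:4], "integer", size = 4L,
      endian = endian
    )
  }
  dims <- vapply(pages, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L])) {
    stop("unsupported TIFF: pages of differing size")
  }
  pixels <- array(0, dim = c(length(pages), dims[1L, 1L], dims[2L, 1L]))
  for (z in seq_along(pages)) pixels[z, , ] <- pages[[z]]
  list(pixels = pixels, description = description, resolution = resolution)
}
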