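#' Calibrated image volume
#'
#' A `volume` is the package's container for a single-channel 3D fluorescence
#' stack: a non-negative intensity grid indexed `(z, y, x)` (zero-based pixel
#' coordinates are used throughout the geometry code: pixel `(i, j)` of a slice
#' has its centre at `x = j - 1`, `y = i - 1` in pixel units) together with the
#' voxel spacing `(dz, dy, dx)` in micrometres. After reorientation the slice
#' index `z` increases along the tube axis.
#'
#' @param voxels 3D numeric array `[z, y, x]`, finite and non-negative, at
#'   least one slice of at least 8 x 8 pixels.
#' @param spacing numeric `(dz, dy, dx)` in micrometres, all positive.
#' @param time_index optional non-negative integer frame index for time-lapse
#'   volumes.
#' @return an object of class `volume`.
#' @examples
#' v <- volume(array(1, dim = c(4, 16, 16)), spacing = c(0.6, 0.2, 0.2))
#' dim(v$voxels)
#' @export
volume <- function(voxels, spacing, time_index = NULL) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(1L, dim(voxels)))
  if (length(dim(voxels)) != 3L) stop("`voxels` must be a 3D array (z, y, x)")
  if (dim(voxels)[2L] < 8L || dim(voxels)[3L] < 8L) {
    stop("in-plane size must be at least 8 x 8 pixels")
  }
  if (!all(is.finite(voxels)) || any(voxels < 0)) {
    stop("voxel intensities must be finite and non-negative")
  }
  storage.mode(voxels) <- "double"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive values (dz, dy, dx) in um")
  }
  if (!is.null(time_index)) {
    stopifnot(length(time_index) == 1L, time_index >= 0)
    time_index <- as.integer(time_index)
  }
  structure(
    list(voxels = voxels, spacing = spacing, time_index = time_index),
    class = "volume"
  )
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<volume> %d slice(s) of %d x %d px, spacing (%.4g, %.4g, %.4g) um\n",
    d[1L], d[2L], d[3L], x$spacing[1L], x$spacing[2L], x$spacing[3L]
  ))
  invisible(x)
}

.parse_imagej_desc <- function(desc) {
  if (is.null(desc)) return(list())
  lines <- strsplit(desc, "\n", fixed = TRUE)[[1L]]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)=(.*)$", lines))
  out <- list()
  for (m in kv) if (length(m) == 3L) out[[m[2L]]] <- m[3L]
  out
}

#' Read a calibrated volume from a TIFF stack
#'
#' Reads an uncompressed grayscale (OME-)TIFF stack, one page per optical Z
#' plane. Calibration is taken, in order of precedence, from
#' `spacing_override`, the ImageJ-style description keys
#' (`spacing`/`pixel_height`/`pixel_width`, unit micron), or the
#' X/YResolution tags (pixels per micron; usable for the in-plane spacing
#' only, so a description `spacing` must also be present). A stack carrying no
#' calibration and no override is an error, as is a single-plane (2D-only)
#' image.
#'
#' @param path TIFF file.
#' @param spacing_override optional `(dz, dy, dx)` in micrometres, used
#'   verbatim.
#' @return a [volume()].
#' @export
read_volume <- function(path, spacing_override = NULL) {
  tf <- read_tiff(path)
  if (dim(tf$pixels)[1L] < 2L) {
    stop("`", path, "` is a 2D-only image; a Z stack is required")
  }
  spacing <- spacing_override
  if (is.null(spacing)) {
    keys <- .parse_imagej_desc(tf$description)
    if (!is.null(keys$spacing)) {
      dz <- as.numeric(keys$spacing)
      if (!is.null(keys$pixel_width) && !is.null(keys$pixel_height)) {
        spacing <- c(dz, as.numeric(keys$pixel_height),
                     as.numeric(keys$pixel_width))
      } else if (!is.null(tf$resolution) && all(tf$resolution > 0)) {
        spacing <- c(dz, 1 / tf$resolution[2L], 1 / tf$resolution[1L])
      }
    }
  }
  if (is.null(spacing)) {
    stop("`", path, "` carries no voxel calibration; ",
         "pass `spacing_override = c(dz, dy, dx)`")
  }
  volume(tf$pixels, spacing)
}

#' Write a calibrated volume as a multi-page TIFF
#'
#' @param vol a [volume()].
#' @param path output file.
#' @param type sample type; integer types round-trip bit-exactly.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, type = c("float32", "uint16", "uint8")) {
  stopifnot(inherits(vol, "volume"))
  type <- match.arg(type)
  write_tiff(vol$voxels, path, spacing = vol$spacing, type = type)
}

#' Junction-spot track
#'
#' One tracked junctional spot: a label (conventionally `"anterior"` or
#' `"posterior"`) and time-ordered samples `(t, x, y)` in minutes and
#' micrometres. Missing timepoints are simply absent rows (gaps).
#'
#' @param label track label.
#' @param t,x,y numeric vectors of equal length; `t` strictly increasing.
#' @return an object of class `spot_track`.
#' @export
spot_track <- function(label, t, x, y) {
  stopifnot(length(t) == length(x), length(t) == length(y))
  if (length(t) == 0L) stop("a track needs at least one sample")
  o <- order(t)
  t <- as.numeric(t[o]); x <- as.numeric(x[o]); y <- as.numeric(y[o])
  if (any(diff(t) <= 0)) stop("track timepoints must be strictly increasing")
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(t))) {
    stop("track samples must be finite")
  }
  structure(
    list(label = as.character(label),
         samples = data.frame(t = t, x = x, y = y)),
    class = "spot_track"
  )
}

#' @export
print.spot_track <- function(x, ...) {
  cat(sprintf("<spot_track> '%s', %d samples, t in [%g, %g] min\n",
              x$label, nrow(x$samples), min(x$samples$t), max(x$samples$t)))
  invisible(x)
}

#' Read spot tracks from a CSV export
#'
#' Consumes the flat CSV dialect `track_id,t,x,y[,label]` (the canonical form
#' of a TrackMate-style export): `t` in minutes, positions in micrometres.
#' When the file carries a `frame` column instead of `t`, frame numbers are
#' converted with `frame_interval` (minutes per frame). Rows may arrive in any
#' order; samples are returned time-sorted per track. A duplicated
#' `(track_id, t)` pair is an error.
#'
#' @param path CSV file.
#' @param frame_interval minutes per frame, used only for `frame` columns
#'   (default 2, the spinning-disk cadence).
#' @return named list of [spot_track()]s, one per `track_id`.
#' @export
read_tracks <- function(path, frame_interval = 2) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!("t" %in% names(df)) && "frame" %in% names(df)) {
    df$t <- df$frame * frame_interval
  }
  need <- c("track_id", "t", "x", "y")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("track table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df[, c("track_id", "t")]) > 0L) {
    stop("duplicated (track_id, t) pair in ", path)
  }
  ids <- unique(df$track_id)
  out <- lapply(ids, function(id) {
    rows <- df[df$track_id == id, , drop = FALSE]
    label <- if ("label" %in% names(rows) && nzchar(rows$label[1L])) {
      rows$label[1L]
    } else {
      as.character(id)
    }
    spot_track(label, rows$t, rows$x, rows$y)
  })
  names(out) <- as.character(ids)
  out
}

#' Write spot tracks to the canonical CSV dialect
#'
#' @param tracks list of [spot_track()]s.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  rows <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    id <- if (!is.null(names(tracks)) && nzchar(names(tracks)[i])) {
      names(tracks)[i]
    } else {
      as.character(i)
    }
    data.frame(track_id = id, t = tr$samples$t, x = tr$samples$x,
               y = tr$samples$y, label = tr$label)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read cell contours from a CSV vertex table
#'
#' Expects `cell_id,vertex_index,x,y[,annotation]` with map coordinates in
#' micrometres; vertices are ordered by `vertex_index` within each cell and
#' every polygon must have at least three vertices. An annotation equal to
#' `"EHT"` (case-insensitive) marks the cell as a user-identified EHT cell.
#'
#' @param path CSV file.
#' @return named list of contours; each element has `xy` (n x 2 matrix, um)
#'   and `eht` (logical).
#' @export
read_contours <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "vertex_index", "x", "y")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("contour table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  ids <- unique(df$cell_id)
  out <- lapply(ids, function(id) {
    rows <- df[df$cell_id == id, , drop = FALSE]
    rows <- rows[order(rows$vertex_index), , drop = FALSE]
    if (nrow(rows) < 3L) stop("cell ", id, " has fewer than 3 vertices")
    eht <- "annotation" %in% names(rows) &&
      any(toupper(trimws(rows$annotation)) == "EHT")
    list(xy = cbind(x = rows$x, y = rows$y), eht = eht)
  })
  names(out) <- as.character(ids)
  out
}

#' Read a plain-text `key = value` configuration file
#'
#' Blank lines and `#` comments are ignored; values that parse as numbers are
#' returned numeric, everything else as character.
#'
#' @param path config file.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln)[[1L]]
    if (m[1L] == -1L) stop("malformed config line: ", ln)
    key <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", ln))[[1L]]
    val <- trimws(key[3L])
    num <- suppressWarnings(as.numeric(val))
    out[[key[2L]]] <- if (!is.na(num)) num else val
  }
  out
}
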