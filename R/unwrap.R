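#' Unwrapped 2D-map
#'
#' The planar cartography of the tube surface: X is the circumferential
#' position along the fitted circles' perimeter, Y the position along the tube
#' central axis, with a single isotropic pixel size (um). Column `k`
#' (1-based) holds the angular bin centred at
#' `theta_origin + (k - 1) * 2 * pi / N`.
#'
#' @param pixels numeric matrix, rows = slices (axial), cols = angular bins.
#' @param pixel_size isotropic pixel pitch, um.
#' @param theta_origin angle mapped to X = 0 (radians; 0 = image +x direction
#'   from each circle centre).
#' @param row_radius per-row source radius (um).
#' @param duplicated has the map been duplicated along X to merge the seam?
#' @return object of class `unwrapped_map`.
#' @export
unwrapped_map <- function(pixels, pixel_size, theta_origin = 0,
                          row_radius = NULL, duplicated = FALSE) {
  stopifnot(is.matrix(pixels), pixel_size > 0)
  if (is.null(row_radius)) row_radius <- rep(NA_real_, nrow(pixels))
  stopifnot(length(row_radius) == nrow(pixels))
  structure(
    list(pixels = pixels, pixel_size = pixel_size,
         theta_origin = theta_origin, row_radius = row_radius,
         duplicated = isTRUE(duplicated)),
    class = "unwrapped_map"
  )
}

#' @export
print.unwrapped_map <- function(x, ...) {
  cat(sprintf(
    "<unwrapped_map> %d x %d px at %.4g um/px%s\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_size,
    if (x$duplicated) " (duplicated)" else ""
  ))
  invisible(x)
}

#' Collect the angular intensity profile of one crown
#'
#' For each of `n_theta` angular bins (bin `k` is centred at
#' `theta_origin + k * 2 * pi / n_theta`, zero-based `k`, and spans half a bin
#' width to each side) the returned value is the maximal intensity over the
#' crown pixels falling in that sector: pixels whose centre lies at distance
#' `r - w/2 .. r + w/2` from the circle centre and whose angle falls in the
#' bin. Intensities are taken as stored — nearest pixel, no interpolation.
#' This sector-max rule is the dense-sampling limit of walking the perimeter
#' at every angle and keeping the crown maximum. A sector containing no pixel
#' centre falls back to nearest-pixel point sampling along the crown
#' (`ceil(w) + 1` radii, sub-bin angular steps of at most half a pixel arc);
#' out-of-domain samples are skipped, and a bin with no sample at all is an
#' error.
#'
#' @param slice_image numeric matrix.
#' @param circle a [crown_circle()].
#' @param n_theta number of angular bins (>= 8).
#' @param theta_origin angle of bin 0 (radians).
#' @return numeric vector of length `n_theta`.
#' @export
sample_ring <- function(slice_image, circle, n_theta, theta_origin = 0) {
  stopifnot(is.matrix(slice_image), inherits(circle, "crown_circle"))
  if (n_theta < 8L) stop("n_theta must be at least 8")
  ny <- nrow(slice_image); nx <- ncol(slice_image)
  lo <- circle$r - circle$crown_width / 2
  hi <- circle$r + circle$crown_width / 2
  d <- .dist_grid(ny, nx, circle$cx, circle$cy)
  sel <- which(d >= lo & d <= hi, arr.ind = TRUE)
  dtheta <- 2 * pi / n_theta
  out <- rep(-Inf, n_theta)
  if (nrow(sel) > 0L) {
    px <- sel[, 2L] - 1; py <- sel[, 1L] - 1
    theta <- atan2(py - circle$cy, px - circle$cx)
    k <- round((theta - theta_origin) / dtheta) %% n_theta
    vals <- slice_image[sel]
    agg <- tapply(vals, k, max)
    out[as.integer(names(agg)) + 1L] <- agg
  }
  empty <- which(!is.finite(out))
  if (length(empty) > 0L) {
    rho <- seq(lo, hi, length.out = ceiling(circle$crown_width) + 1L)
    n_sub <- max(3L, ceiling(hi * dtheta / 0.5))
    for (k in empty - 1L) {
      th <- theta_origin + k * dtheta +
        seq(-dtheta / 2, dtheta / 2, length.out = n_sub)
      pts <- expand.grid(rho = rho, th = th)
      sx <- round(circle$cx + pts$rho * cos(pts$th))
      sy <- round(circle$cy + pts$rho * sin(pts$th))
      okp <- sx >= 0 & sx <= nx - 1 & sy >= 0 & sy <= ny - 1
      if (!any(okp)) next
      out[k + 1L] <- max(slice_image[cbind(sy[okp] + 1L, sx[okp] + 1L)])
    }
    if (any(!is.finite(out))) {
      stop("angular bin with no in-domain sample (crown outside the image?)")
    }
  }
  out
}

#' Unwrap a fitted tube into a 2D-map
#'
#' Builds the planar map: row `y` is the angular profile ([sample_ring()]) of
#' slice `y`'s fitted circle, written onto a common grid of
#' `N = round(2 * pi * rbar / pixel_size)` angular bins, where `rbar` is the
#' tube's reference radius (median fitted radius, um) and the pixel size
#' defaults to the axial slice spacing `dz` — which makes the calibration
#' isotropic at the reference radius. Rows whose radius differs from `rbar`
#' are sampled at their own radius onto the same angular bins (the per-row
#' arc-length distortion `r / rbar` is recorded in `row_radius`).
#'
#' @param vol a [volume()].
#' @param tube a [tube_model()] covering `vol`'s slices.
#' @param pixel_size map pixel pitch in um (default: `dz`).
#' @param theta_origin angle mapped to X = 0.
#' @param reference_radius override for `rbar` in um (used by
#'   [unwrap_timelapse()] to impose a common width).
#' @return an [unwrapped_map()]; height = number of fitted slices, width = N.
#' @export
unwrap_volume <- function(vol, tube, pixel_size = NULL, theta_origin = 0,
                          reference_radius = NULL) {
  stopifnot(inherits(vol, "volume"), inherits(tube, "tube_model"))
  if (nrow(tube$circles) == 0L) stop("empty tube model")
  if (is.null(pixel_size)) pixel_size <- vol$spacing[1L]
  rbar <- if (is.null(reference_radius)) tube$reference_radius else reference_radius
  n_theta <- as.integer(round(2 * pi * rbar / pixel_size))
  if (n_theta < 8L) stop("map would be narrower than 8 px; check calibration")
  circ <- tube$circles
  pix <- matrix(0, nrow = nrow(circ), ncol = n_theta)
  for (i in seq_len(nrow(circ))) {
    cc <- crown_circle(circ$cx[i], circ$cy[i], circ$r[i], tube$crown_width,
                       z = circ$z[i])
    pix[i, ] <- sample_ring(vol$voxels[circ$z[i] + 1L, , , drop = TRUE], cc,
                            n_theta, theta_origin = theta_origin)
  }
  unwrapped_map(pix, pixel_size, theta_origin = theta_origin,
                row_radius = circ$r * vol$spacing[3L])
}

#' Duplicate a map along X to merge the seam
#'
#' Appends a full copy of the map to its right so that any cell contour
#' crossing the circumferential seam (theta = 0) can be traced as one
#' continuous polygon. Duplicating twice is an error.
#'
#' @param map an [unwrapped_map()].
#' @return duplicated [unwrapped_map()] (width doubled).
#' @export
duplicate_map <- function(map) {
  stopifnot(inherits(map, "unwrapped_map"))
  if (map$duplicated) stop("map is already duplicated")
  unwrapped_map(cbind(map$pixels, map$pixels), map$pixel_size,
                theta_origin = map$theta_origin, row_radius = map$row_radius,
                duplicated = TRUE)
}

#' Unwrap a time-lapse sequence with frame-to-frame initialisation
#'
#' Frame `t`'s first-slice fit is initialised from frame `t - 1`'s (the
#' semi-automatic adjustment carried through time); each frame gets its own
#' tube model, and a common reference radius (the median of the per-frame
#' reference radii) fixes one map width for the whole sequence.
#'
#' @param volumes time-ordered list of [volume()]s sharing calibration.
#' @param init [crown_circle()] for the first frame's first slice.
#' @param ... passed to [propagate_fit()].
#' @param pixel_size,theta_origin see [unwrap_volume()].
#' @return list with `maps` (list of [unwrapped_map()]), `tubes` (list of
#'   [tube_model()]) and `reference_radius` (common, um).
#' @export
unwrap_timelapse <- function(volumes, init, ..., pixel_size = NULL,
                             theta_origin = 0) {
  stopifnot(length(volumes) >= 1L)
  sp <- volumes[[1L]]$spacing
  for (v in volumes) {
    if (max(abs(v$spacing - sp)) > 1e-9) stop("frames must share calibration")
  }
  tubes <- vector("list", length(volumes))
  cur <- init
  for (f in seq_along(volumes)) {
    tubes[[f]] <- propagate_fit(volumes[[f]], cur, ...)
    c1 <- tubes[[f]]$circles[1L, ]
    cur <- crown_circle(c1$cx, c1$cy, c1$r, init$crown_width)
  }
  rbar <- stats::median(vapply(tubes, function(tb) tb$reference_radius,
                               numeric(1L)))
  maps <- lapply(seq_along(volumes), function(f) {
    unwrap_volume(volumes[[f]], tubes[[f]], pixel_size = pixel_size,
                  theta_origin = theta_origin, reference_radius = rbar)
  })
  list(maps = maps, tubes = tubes, reference_radius = rbar)
}

#' Write a map as a single-channel TIFF plus a sidecar CSV
#'
#' The sidecar (`<path>.meta.csv`) records pixel size, theta origin, the
#' duplication flag and each row's source radius.
#'
#' @param map an [unwrapped_map()].
#' @param path TIFF output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "unwrapped_map"))
  write_tiff(map$pixels, path,
             spacing = c(map$pixel_size, map$pixel_size, map$pixel_size))
  meta <- data.frame(
    row = seq_len(nrow(map$pixels)) - 1L,
    pixel_size = map$pixel_size,
    theta_origin = map$theta_origin,
    duplicated = map$duplicated,
    row_radius = map$row_radius
  )
  utils::write.csv(meta, paste0(path, ".meta.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
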