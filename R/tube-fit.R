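#' Crown-constrained circle
#'
#' The wall of the vessel is located slice by slice as a circle with a "crown":
#' an annulus of width `crown_width` centred on the circle's radius. The fit
#' maximises fluorescence inside the crown while penalising fluorescence in the
#' inner disk, which pins the circle to the bright membrane ring of the tube
#' cross-section. Coordinates are zero-based pixels in the slice plane.
#'
#' @param cx,cy circle centre (px).
#' @param r radius (px), `r - crown_width/2` must stay positive.
#' @param crown_width crown (annulus) width (px), default 3 — about one
#'   membrane thickness at typical sampling.
#' @param z slice index (zero-based) the circle belongs to, or `NA`.
#' @param score objective value, filled by the fitting routines.
#' @param flagged `TRUE` when the circle was carried over from the previous
#'   slice because the fit fell below the quality floor.
#' @return an object of class `crown_circle`.
#' @export
crown_circle <- function(cx, cy, r, crown_width = 3, z = NA_integer_,
                         score = NA_real_, flagged = FALSE) {
  stopifnot(is.finite(cx), is.finite(cy), is.finite(r), is.finite(crown_width))
  if (r <= 0) stop("radius must be positive")
  if (crown_width <= 0) stop("crown width must be positive")
  if (r - crown_width / 2 <= 0) stop("crown must not swallow the centre (r - w/2 <= 0)")
  structure(
    list(cx = cx, cy = cy, r = r, crown_width = crown_width,
         z = z, score = score, flagged = flagged),
    class = "crown_circle"
  )
}

#' @export
print.crown_circle <- function(x, ...) {
  cat(sprintf(
    "<crown_circle> z=%s centre=(%.2f, %.2f) r=%.2f w=%.2f score=%.4g%s\n",
    ifelse(is.na(x$z), "?", x$z), x$cx, x$cy, x$r, x$crown_width, x$score,
    if (isTRUE(x$flagged)) " [flagged]" else ""
  ))
  invisible(x)
}

.circle_in_domain <- function(circle, ny, nx) {
  out <- circle$r + circle$crown_width / 2
  circle$cx - out >= 0 && circle$cx + out <= nx - 1 &&
    circle$cy - out >= 0 && circle$cy + out <= ny - 1
}

# distance-to-centre grid for one slice; pixel (i, j) sits at (x=j-1, y=i-1)
.dist_grid <- function(ny, nx, cx, cy) {
  dx2 <- (seq_len(nx) - 1 - cx)^2
  dy2 <- (seq_len(ny) - 1 - cy)^2
  sqrt(outer(dy2, dx2, "+"))
}

#' Crown objective for a candidate circle
#'
#' Scores a circle on one slice: fluorescence collected in the crown
#' (`r - w/2 <= d <= r + w/2`, Euclidean distance of the pixel centre to the
#' circle centre) minus `lambda` times the fluorescence of the inner disk
#' (`d < r - w/2`). With `normalize = TRUE` (default) both terms are
#' mean-normalised (sum divided by pixel count) so that the differing pixel
#' counts of crown and disk do not dominate; `lambda = 1` then weighs the two
#' stated goals equally and the score is scale-free in the image area.
#'
#' @param slice_image numeric matrix (rows = y, columns = x).
#' @param circle a [crown_circle()], whole crown inside the image domain.
#' @param lambda inner-disk penalty weight (default 1).
#' @param normalize use per-pixel means instead of raw sums.
#' @return scalar score (0 on an all-zero slice).
#' @export
crown_objective <- function(slice_image, circle, lambda = 1, normalize = TRUE) {
  stopifnot(is.matrix(slice_image), inherits(circle, "crown_circle"))
  ny <- nrow(slice_image); nx <- ncol(slice_image)
  if (!.circle_in_domain(circle, ny, nx)) {
    stop("circle (including crown) leaves the image domain")
  }
  d <- .dist_grid(ny, nx, circle$cx, circle$cy)
  lo <- circle$r - circle$crown_width / 2
  hi <- circle$r + circle$crown_width / 2
  crown <- d >= lo & d <= hi
  inner <- d < lo
  n_crown <- sum(crown)
  if (n_crown == 0L) stop("crown contains no pixels")
  s_crown <- sum(slice_image[crown])
  s_inner <- sum(slice_image[inner])
  if (normalize) {
    n_inner <- sum(inner)
    s_crown / n_crown - lambda * (if (n_inner > 0L) s_inner / n_inner else 0)
  } else {
    s_crown - lambda * s_inner
  }
}

#' Fit a crown circle on one slice by local grid search
#'
#' Exhaustively scores every candidate on the discrete grid
#' `cx + {-sc..sc}`, `cy + {-sc..sc}`, `r + {-sr..sr}` (step `step`, px) around
#' the initialisation and returns the argmax of [crown_objective()].
#' Candidates whose crown leaves the image are discarded. Ties are broken
#' toward the candidate closest to the initialisation (Euclidean in
#' `(cx, cy, r)`), then lexicographically by `(cx, cy, r)`; on a flat
#' objective the initialisation is therefore returned unchanged. The returned
#' score is never below the initialisation's own score.
#'
#' @param slice_image numeric matrix.
#' @param init initial [crown_circle()] (the user's manual adjustment, the
#'   previous slice's fit, or ground truth).
#' @param search_center half-width of the centre search (px).
#' @param search_radius half-width of the radius search (px); 0 holds the
#'   radius fixed.
#' @param step grid step (px).
#' @param lambda,normalize passed to [crown_objective()].
#' @return fitted [crown_circle()] with `score` set.
#' @export
fit_circle_slice <- function(slice_image, init, search_center = 3,
                             search_radius = 3, step = 1, lambda = 1,
                             normalize = TRUE) {
  stopifnot(inherits(init, "crown_circle"))
  ny <- nrow(slice_image); nx <- ncol(slice_image)
  dc <- seq(-search_center, search_center, by = step)
  dr <- seq(-search_radius, search_radius, by = step)
  grid <- expand.grid(dcx = dc, dcy = dc, dr = dr)
  cand <- data.frame(
    cx = init$cx + grid$dcx, cy = init$cy + grid$dcy, r = init$r + grid$dr
  )
  w <- init$crown_width
  ok <- cand$r - w / 2 > 0 &
    cand$cx - (cand$r + w / 2) >= 0 & cand$cx + (cand$r + w / 2) <= nx - 1 &
    cand$cy - (cand$r + w / 2) >= 0 & cand$cy + (cand$r + w / 2) <= ny - 1
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0L) stop("no feasible candidate in the search grid")
  scores <- vapply(seq_len(nrow(cand)), function(i) {
    crown_objective(
      slice_image,
      crown_circle(cand$cx[i], cand$cy[i], cand$r[i], w),
      lambda = lambda, normalize = normalize
    )
  }, numeric(1L))
  best <- which(scores == max(scores))
  if (length(best) > 1L) {
    d0 <- (cand$cx[best] - init$cx)^2 + (cand$cy[best] - init$cy)^2 +
      (cand$r[best] - init$r)^2
    best <- best[d0 == min(d0)]
    if (length(best) > 1L) {
      o <- order(cand$cx[best], cand$cy[best], cand$r[best])
      best <- best[o[1L]]
    }
  }
  crown_circle(cand$cx[best], cand$cy[best], cand$r[best], w,
               z = init$z, score = scores[best])
}

#' Tube model: fitted circles and central axis
#'
#' @param circles data.frame `z, cx, cy, r, score, flagged` (px, zero-based
#'   slice index, strictly increasing).
#' @param spacing voxel spacing `(dz, dy, dx)` um of the fitted volume
#'   (`dy == dx` required; circles live in the image plane).
#' @param crown_width crown width used for the fits (px).
#' @return object of class `tube_model` with `axis` (n x 3 matrix of centre
#'   positions in um, columns `x, y, z`) and `reference_radius` (median fitted
#'   radius, um).
#' @export
tube_model <- function(circles, spacing, crown_width) {
  stopifnot(is.data.frame(circles), nrow(circles) >= 1L)
  if (is.unsorted(circles$z, strictly = TRUE)) {
    stop("slice indices must be strictly increasing")
  }
  if (abs(spacing[2L] - spacing[3L]) > 1e-9) {
    stop("anisotropic in-plane spacing (dy != dx) is not supported: ",
         "circles are defined in the image plane")
  }
  axis <- cbind(
    x = circles$cx * spacing[3L],
    y = circles$cy * spacing[2L],
    z = circles$z * spacing[1L]
  )
  structure(
    list(circles = circles, spacing = spacing, crown_width = crown_width,
         axis = axis,
         reference_radius = stats::median(circles$r) * spacing[3L]),
    class = "tube_model"
  )
}

#' @export
print.tube_model <- function(x, ...) {
  cat(sprintf(
    "<tube_model> %d slice(s), reference radius %.3f um, %d flagged\n",
    nrow(x$circles), x$reference_radius, sum(x$circles$flagged)
  ))
  invisible(x)
}

#' Propagate the circle fit along the tube
#'
#' Fits slice 0 from `init`, then walks down the stack using each slice's
#' result as the next slice's initialisation — the repeated per-section fit
#' that locates the tube's central axis. A slice whose best score falls below
#' `quality_floor` keeps its predecessor's circle and is flagged; the first
#' slice falling below the floor is an error. The per-slice radius search is
#' clamped to `max_radius_step` so consecutive radii never jump by more.
#'
#' @param vol a [volume()] (requires `dy == dx`).
#' @param init [crown_circle()] for the first slice.
#' @param quality_floor minimum acceptable score (default `-Inf`: accept all).
#' @param search_center,search_radius,step,lambda,normalize see
#'   [fit_circle_slice()]; `refit_radius = FALSE` freezes the radius after the
#'   first slice.
#' @param max_radius_step maximum |r(z+1) - r(z)| (px).
#' @param refit_radius re-fit the radius on every slice (default) or hold it.
#' @return a [tube_model()].
#' @export
propagate_fit <- function(vol, init, quality_floor = -Inf, search_center = 3,
                          search_radius = 3, step = 1, lambda = 1,
                          normalize = TRUE, max_radius_step = 2,
                          refit_radius = TRUE) {
  stopifnot(inherits(vol, "volume"), inherits(init, "crown_circle"))
  if (abs(vol$spacing[2L] - vol$spacing[3L]) > 1e-9) {
    stop("anisotropic in-plane spacing (dy != dx) is not supported")
  }
  nz <- dim(vol$voxels)[1L]
  sr <- if (refit_radius) min(search_radius, max_radius_step) else 0
  rows <- vector("list", nz)
  prev <- init
  for (z in seq_len(nz)) {
    prev$z <- z - 1L
    fit <- fit_circle_slice(
      vol$voxels[z, , , drop = TRUE], prev,
      search_center = search_center, search_radius = sr, step = step,
      lambda = lambda, normalize = normalize
    )
    if (fit$score < quality_floor) {
      if (z == 1L) stop("first slice scored below the quality floor")
      fit <- prev
      fit$flagged <- TRUE
      fit$z <- z - 1L
    }
    rows[[z]] <- data.frame(
      z = z - 1L, cx = fit$cx, cy = fit$cy, r = fit$r,
      score = fit$score, flagged = fit$flagged
    )
    prev <- fit
    prev$flagged <- FALSE
  }
  tube_model(do.call(rbind, rows), vol$spacing, init$crown_width)
}

#' Serialize / read back a tube model audit table
#'
#' @param tube a [tube_model()].
#' @param path CSV path (`z,cx,cy,r,score,flagged`).
#' @return `path` invisibly / a data.frame.
#' @export
write_tube_csv <- function(tube, path) {
  stopifnot(inherits(tube, "tube_model"))
  utils::write.csv(tube$circles, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tube_csv
#' @export
read_tube_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reorient a volume so the tube axis runs along Z
#'
#' `axis_spec` is either a permutation string over `"zyx"` naming, for each
#' output axis, the input axis it takes (e.g. `"yzx"`: the new slice axis is
#' the old y — the sweep direction for a tube laid along y), or
#' `list(axis = "z"|"y"|"x", angle = degrees)` for a small rotation about one
#' coordinate axis, resampled by nearest neighbour in physical (um)
#' coordinates on the same grid. `"zyx"` is the identity. Rotation output
#' keeps the input dims and spacing; voxels sampling outside the input domain
#' are 0, and a rotation after which no output slice keeps at least half its
#' voxels covered by data is an error.
#'
#' @param vol a [volume()].
#' @param axis_spec permutation string or `list(axis=, angle=)`.
#' @return reoriented [volume()].
#' @export
reorient <- function(vol, axis_spec = "zyx") {
  stopifnot(inherits(vol, "volume"))
  if (is.character(axis_spec)) {
    ax <- strsplit(axis_spec, "")[[1L]]
    if (length(ax) != 3L || !setequal(ax, c("z", "y", "x"))) {
      stop("permutation must be a string over 'zyx', e.g. 'yzx'")
    }
    perm <- match(ax, c("z", "y", "x"))
    return(volume(aperm(vol$voxels, perm), vol$spacing[perm],
                  time_index = vol$time_index))
  }
  stopifnot(is.list(axis_spec), !is.null(axis_spec$axis),
            !is.null(axis_spec$angle))
  theta <- axis_spec$angle * pi / 180
  d <- dim(vol$voxels)
  sp <- vol$spacing
  # physical coordinates of voxel centres, origin at the grid centre
  zc <- (seq_len(d[1L]) - 1 - (d[1L] - 1) / 2) * sp[1L]
  yc <- (seq_len(d[2L]) - 1 - (d[2L] - 1) / 2) * sp[2L]
  xc <- (seq_len(d[3L]) - 1 - (d[3L] - 1) / 2) * sp[3L]
  grid <- expand.grid(z = zc, y = yc, x = xc)
  ct <- cos(-theta); st <- sin(-theta)   # inverse rotation: output -> input
  src <- switch(axis_spec$axis,
    z = cbind(z = grid$z, y = ct * grid$y - st * grid$x,
              x = st * grid$y + ct * grid$x),
    y = cbind(z = ct * grid$z + st * grid$x, y = grid$y,
              x = -st * grid$z + ct * grid$x),
    x = cbind(z = ct * grid$z - st * grid$y, y = st * grid$z + ct * grid$y,
              x = grid$x),
    stop("rotation axis must be 'z', 'y' or 'x'")
  )
  iz <- round(src[, "z"] / sp[1L] + (d[1L] - 1) / 2) + 1
  iy <- round(src[, "y"] / sp[2L] + (d[2L] - 1) / 2) + 1
  ix <- round(src[, "x"] / sp[3L] + (d[3L] - 1) / 2) + 1
  inside <- iz >= 1 & iz <= d[1L] & iy >= 1 & iy <= d[2L] &
    ix >= 1 & ix <= d[3L]
  vals <- numeric(nrow(src))
  vals[inside] <- vol$voxels[cbind(iz[inside], iy[inside], ix[inside])]
  out <- array(vals, dim = d)
  cover <- array(inside, dim = d)
  covered <- vapply(seq_len(d[1L]), function(z) mean(cover[z, , ]),
                    numeric(1L))
  if (!any(covered >= 0.5)) stop("rotation leaves no usable slice of data")
  volume(out, sp, time_index = vol$time_index)
}
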