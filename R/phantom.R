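#' Specification of a synthetic tube phantom
#'
#' The phantom emulates a junctional-reporter recording of the dorsal aorta:
#' a roughly cylindrical shell of bright membrane signal whose surface is
#' tessellated into cells (Voronoi mosaic on the unrolled cylinder, borders
#' brighter than cell interiors, tricellular vertices brighter still — the
#' junctional spots), with optional axis drift and radius variation along the
#' tube, Gaussian blur and additive Gaussian noise. Defaults mirror the
#' recording conditions the package targets: 0.6 um optical sections, 0.2 um
#' in-plane pixels, a tube radius around 11 um (the embryonic aorta is
#' ~25 um across), and a mosaic coarse enough that the circumference spans
#' about three cells.
#'
#' @param n_slices number of optical sections.
#' @param image_size `(ny, nx)` slice size in px.
#' @param spacing `(dz, dy, dx)` um; `dy == dx` required.
#' @param radius radius profile in px: scalar or vector of length `n_slices`.
#' @param center centre profile: length-2 `(cx, cy)` px or `n_slices` x 2
#'   matrix.
#' @param membrane_amplitude intensity of cell-border membrane signal.
#' @param interior_fraction shell intensity of cell interiors, as a fraction
#'   of `membrane_amplitude` (cortical background signal).
#' @param membrane_thickness shell thickness in px.
#' @param n_cells number of Voronoi seeds on the cylinder surface.
#' @param junction_spot_gain brightness multiplier at tricellular vertices.
#' @param border_width half-width of the border enhancement, um (geodesic).
#' @param cell_aspect anisotropy of the seed lattice: > 1 stretches cells
#'   along the tube axis (the elongated endothelial mosaic).
#' @param psf_sigma in-plane Gaussian blur sigma, px (0 = none).
#' @param noise_sigma additive Gaussian noise sigma (0 = none).
#' @param background constant background offset.
#' @param floor_theta circumferential angle of the ventral floor (radians).
#' @param seed RNG seed; fixes the volume bit-exactly.
#' @return object of class `tube_phantom_spec`.
#' @export
tube_phantom_spec <- function(n_slices = 20, image_size = c(96, 96),
                              spacing = c(0.6, 0.2, 0.2), radius = 40,
                              center = NULL, membrane_amplitude = 100,
                              interior_fraction = 0.35,
                              membrane_thickness = 3, n_cells = 12,
                              junction_spot_gain = 2, border_width = 0.5,
                              cell_aspect = 2, psf_sigma = 0,
                              noise_sigma = 0, background = 5,
                              floor_theta = pi / 2, seed = 1) {
  if (is.null(center)) center <- (image_size[c(2L, 1L)] - 1) / 2
  radius <- rep_len(radius, n_slices)
  if (is.null(dim(center))) {
    center <- matrix(rep(center, each = n_slices), ncol = 2L)
  }
  stopifnot(nrow(center) == n_slices, ncol(center) == 2L)
  if (abs(spacing[2L] - spacing[3L]) > 1e-9) stop("dy must equal dx")
  if (any(radius - membrane_thickness / 2 <= 0)) {
    stop("radius must exceed half the membrane thickness everywhere")
  }
  out <- radius + membrane_thickness / 2
  if (any(center[, 1L] - out < 0 | center[, 1L] + out > image_size[2L] - 1 |
          center[, 2L] - out < 0 | center[, 2L] + out > image_size[1L] - 1)) {
    stop("tube (including membrane) leaves the image domain")
  }
  structure(
    list(n_slices = n_slices, image_size = image_size, spacing = spacing,
         radius = radius, center = center,
         membrane_amplitude = membrane_amplitude,
         interior_fraction = interior_fraction,
         membrane_thickness = membrane_thickness, n_cells = n_cells,
         junction_spot_gain = junction_spot_gain,
         border_width = border_width, cell_aspect = cell_aspect,
         psf_sigma = psf_sigma, noise_sigma = noise_sigma,
         background = background, floor_theta = floor_theta, seed = seed),
    class = "tube_phantom_spec"
  )
}

# separable 2D Gaussian blur with edge renormalisation
.gauss_blur2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  rad <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-rad:rad, sd = sigma)
  k <- k / sum(k)
  blur1 <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wsum <- numeric(n)
    for (o in -rad:rad) {
      src <- pmin(pmax(seq_len(n) + o, 1L), n)  # replicate edges
      out <- out + k[o + rad + 1L] * m[src, , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(img))))
}

#' Generate a ground-truthed cylindrical vessel phantom
#'
#' @param spec a [tube_phantom_spec()].
#' @return list with `volume` (a [volume()]) and `truth`: `centerline`
#'   (data.frame `z, cx, cy` px), `radius_px`, `reference_radius_um`,
#'   `circumference_um`, `seeds` (`u, z` um on the unrolled cylinder, u along
#'   the circumference), `tiles` (per-cell Voronoi polygons, um, possibly
#'   extending across the wrap in u), `borders` (data.frame of Voronoi edge
#'   segments `x1, y1, x2, y2`, um), `floor_u` (floor coordinate, um) and
#'   `floor_flags` (per cell: spans the floor while staying within the
#'   medio-lateral band).
#' @export
make_tube_phantom <- function(spec) {
  stopifnot(inherits(spec, "tube_phantom_spec"))
  set.seed(spec$seed)
  ny <- spec$image_size[1L]; nx <- spec$image_size[2L]
  nz <- spec$n_slices
  dz <- spec$spacing[1L]; dx <- spec$spacing[3L]
  rbar_um <- stats::median(spec$radius) * dx
  C_um <- 2 * pi * rbar_um
  L_um <- (nz - 1) * dz

  # anisotropic stratified seeds on the unrolled cylinder (u in [0, C))
  n <- spec$n_cells
  u0 <- stats::runif(n, 0, C_um)
  z0 <- stats::runif(n, 0, L_um)
  # cell_aspect > 1 shrinks the u spread around the stratified grid: emulate
  # by pulling seeds toward equally spaced u bands
  if (spec$cell_aspect != 1) {
    bands <- (seq_len(n) - 0.5) / n * C_um
    w <- 1 / spec$cell_aspect
    u0 <- (w * u0 + (1 - w) * bands[sample.int(n)]) %% C_um
  }

  wrapped_u <- c(u0 - C_um, u0, u0 + C_um)
  wrapped_z <- rep(z0, 3L)
  dd <- deldir::deldir(wrapped_u, wrapped_z,
                       rw = c(-C_um, 2 * C_um, min(0, min(z0)) - 1,
                              max(L_um, max(z0)) + 1))
  tl <- deldir::tile.list(dd)
  central <- n + seq_len(n)
  tiles <- lapply(tl[central], function(tile) cbind(x = tile$x, y = tile$y))
  sg <- dd$dirsgs
  keep <- sg$ind1 %in% central | sg$ind2 %in% central
  borders <- data.frame(x1 = sg$x1[keep], y1 = sg$y1[keep],
                        x2 = sg$x2[keep], y2 = sg$y2[keep])

  floor_u <- (spec$floor_theta %% (2 * pi)) * rbar_um
  frame <- map_frame(C_um, floor_u)
  floor_flags <- vapply(tiles, function(xy) {
    classify_cell(xy, frame) == "hemogenic"
  }, logical(1L))

  vox <- array(0, dim = c(nz, ny, nx))
  half <- spec$membrane_thickness / 2
  for (z in seq_len(nz)) {
    cx <- spec$center[z, 1L]; cy <- spec$center[z, 2L]
    r <- spec$radius[z]
    d <- .dist_grid(ny, nx, cx, cy)
    img <- matrix(spec$background, ny, nx)
    shell <- which(abs(d - r) <= half, arr.ind = TRUE)
    if (nrow(shell) > 0L) {
      px <- shell[, 2L] - 1; py <- shell[, 1L] - 1
      theta <- atan2(py - cy, px - cx) %% (2 * pi)
      u <- theta * rbar_um
      zz <- rep((z - 1) * dz, length(u))
      d2seed <- outer(u, wrapped_u, function(a, b) (a - b)^2) +
        outer(zz, wrapped_z, function(a, b) (a - b)^2)
      d3 <- t(apply(d2seed, 1L, function(row) sqrt(sort(row, partial = 1:3)[1:3])))
      lvl <- rep(spec$interior_fraction * spec$membrane_amplitude,
                 nrow(shell))
      on_border <- d3[, 2L] - d3[, 1L] < spec$border_width
      lvl[on_border] <- spec$membrane_amplitude
      on_vertex <- d3[, 3L] - d3[, 1L] < spec$border_width
      lvl[on_vertex] <- spec$membrane_amplitude * spec$junction_spot_gain
      img[shell] <- img[shell] + lvl
    }
    img <- .gauss_blur2d(img, spec$psf_sigma)
    vox[z, , ] <- img
  }
  if (spec$noise_sigma > 0) {
    vox <- vox + stats::rnorm(length(vox), sd = spec$noise_sigma)
    vox <- pmax(vox, 0)
  }
  list(
    volume = volume(vox, spec$spacing),
    truth = list(
      centerline = data.frame(z = seq_len(nz) - 1L,
                              cx = spec$center[, 1L], cy = spec$center[, 2L]),
      radius_px = spec$radius,
      reference_radius_um = rbar_um,
      circumference_um = C_um,
      seeds = data.frame(u = u0, z = z0),
      tiles = tiles,
      borders = borders,
      floor_u = floor_u,
      floor_flags = floor_flags
    )
  )
}

#' Specification of a synthetic junction-spot track pair
#'
#' Emulates the anterior/posterior junctional spot pair of a constricting
#' cell: the pole-to-pole distance follows a phase plan of contraction and
#' relative-stabilization (pseudo-plateau) phases, carries a planted
#' oscillation of period `period` minutes, and each spot is sampled every
#' `sampling_interval` minutes with positional noise and random dropouts
#' (sporadic loss of signal).
#'
#' @param duration total duration, minutes.
#' @param sampling_interval minutes between frames (default 2).
#' @param initial_distance starting pole-to-pole distance, um.
#' @param plan data.frame `phase, duration, rate`: phase is `"contraction"`
#'   or `"plateau"`, `duration` in minutes, `rate` the distance shrink rate in
#'   um/min during the phase. Defaults to contraction / plateau /
#'   contraction.
#' @param oscillation_amplitude um (0 = pure monotone closing).
#' @param period oscillation period, minutes (> 2 x sampling interval).
#' @param dropout_probability per-sample, per-track dropout probability.
#' @param positional_noise_sigma um, per coordinate.
#' @param seed RNG seed.
#' @return object of class `track_phantom_spec`.
#' @export
track_phantom_spec <- function(duration = 300, sampling_interval = 2,
                               initial_distance = 10, plan = NULL,
                               oscillation_amplitude = 0.3, period = 40,
                               dropout_probability = 0.02,
                               positional_noise_sigma = 0.05, seed = 1) {
  if (is.null(plan)) {
    plan <- data.frame(
      phase = c("contraction", "plateau", "contraction"),
      duration = c(duration * 0.4, duration * 0.2, duration * 0.4),
      rate = c(0.03, 0.005, 0.03)
    )
  }
  stopifnot(all(plan$phase %in% c("contraction", "plateau")),
            all(plan$duration > 0), sum(plan$duration) >= duration)
  if (period <= 2 * sampling_interval) {
    stop("period must exceed twice the sampling interval")
  }
  structure(
    list(duration = duration, sampling_interval = sampling_interval,
         initial_distance = initial_distance, plan = plan,
         oscillation_amplitude = oscillation_amplitude, period = period,
         dropout_probability = dropout_probability,
         positional_noise_sigma = positional_noise_sigma, seed = seed),
    class = "track_phantom_spec"
  )
}

# plan-integrated drift at times t (um lost since t = 0)
.plan_drift <- function(plan, t) {
  bounds <- c(0, cumsum(plan$duration))
  drift <- numeric(length(t))
  for (i in seq_len(nrow(plan))) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    inside <- pmin(pmax(t, lo), hi) - lo
    drift <- drift + plan$rate[i] * inside
  }
  drift
}

#' Generate a ground-truthed oscillatory spot-track pair
#'
#' `d(t) = initial_distance - drift(t) + A * sin(2 * pi * t / period)` with
#' `drift` the plan-integrated contraction; the two spots sit symmetrically at
#' `x = -d/2` and `x = +d/2` (y = 0) plus i.i.d. positional noise, and each
#' sample of each track is dropped independently with
#' `dropout_probability`. A plan driving the distance below zero is an error.
#'
#' @param spec a [track_phantom_spec()].
#' @return list with `anterior`, `posterior` ([spot_track()]s) and `truth`:
#'   `t`, `d` (noise-free distance at every frame), `minima_times` (analytic
#'   interior minima of the planted closing speed, spaced exactly one period)
#'   and `period`.
#' @export
make_track_pair <- function(spec) {
  stopifnot(inherits(spec, "track_phantom_spec"))
  set.seed(spec$seed)
  t <- seq(0, spec$duration, by = spec$sampling_interval)
  fine <- seq(0, spec$duration, by = spec$sampling_interval / 20)
  d_of <- function(tt) {
    spec$initial_distance - .plan_drift(spec$plan, tt) +
      spec$oscillation_amplitude * sin(2 * pi * tt / spec$period)
  }
  if (min(d_of(fine)) < 0) stop("plan drives the distance below zero")
  d <- d_of(t)
  minima <- if (spec$oscillation_amplitude > 0) {
    k <- seq_len(floor(spec$duration / spec$period))
    kt <- k * spec$period
    kt[kt > 0 & kt < spec$duration]
  } else {
    numeric(0)
  }
  sigma <- spec$positional_noise_sigma
  xa <- -d / 2 + stats::rnorm(length(t), sd = sigma)
  ya <- stats::rnorm(length(t), sd = sigma)
  xp <- d / 2 + stats::rnorm(length(t), sd = sigma)
  yp <- stats::rnorm(length(t), sd = sigma)
  keep_a <- stats::runif(length(t)) >= spec$dropout_probability
  keep_p <- stats::runif(length(t)) >= spec$dropout_probability
  if (!any(keep_a) || !any(keep_p)) stop("dropout removed an entire track")
  list(
    anterior = spot_track("anterior", t[keep_a], xa[keep_a], ya[keep_a]),
    posterior = spot_track("posterior", t[keep_p], xp[keep_p], yp[keep_p]),
    truth = list(t = t, d = d, minima_times = minima, period = spec$period)
  )
}
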