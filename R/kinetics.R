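#' Antero-posterior luminal distance series
#'
#' Distance between the paired anterior/posterior junction spots at their
#' common timepoints (minutes, micrometres). Timepoints missing from either
#' track are gaps: the series is split into contiguous runs (successive
#' samples one `sampling_interval` apart) and no downstream operation bridges
#' a gap.
#'
#' @param t,d numeric vectors, `t` strictly increasing, `d >= 0`.
#' @param sampling_interval nominal acquisition interval, minutes.
#' @return object of class `distance_series` (data.frame `t, d` with a
#'   `sampling_interval` attribute).
#' @export
distance_series <- function(t, d, sampling_interval) {
  stopifnot(length(t) == length(d), length(t) >= 1L)
  if (any(diff(t) <= 0)) stop("timepoints must be strictly increasing")
  if (any(d < 0)) stop("distances must be non-negative")
  stopifnot(sampling_interval > 0)
  structure(data.frame(t = as.numeric(t), d = as.numeric(d)),
            sampling_interval = sampling_interval,
            class = c("distance_series", "data.frame"))
}

# indices of contiguous runs: successive samples ~one interval apart
.series_runs <- function(t, interval) {
  if (length(t) == 1L) return(list(1L))
  brk <- which(diff(t) > interval * 1.5 + 1e-9)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(t))
  mapply(function(s, e) s:e, starts, ends, SIMPLIFY = FALSE)
}

#' Pair two spot tracks into a distance series
#'
#' Euclidean distance between the anterior and posterior spots at every
#' timepoint present in both tracks; a timepoint missing from either track
#' (sporadic loss of signal) becomes a gap. Zero common timepoints is an
#' error.
#'
#' @param anterior,posterior [spot_track()]s on the same time base.
#' @param sampling_interval acquisition interval in minutes; by default the
#'   smallest time step seen in either track.
#' @return a [distance_series()].
#' @export
pair_distance <- function(anterior, posterior, sampling_interval = NULL) {
  stopifnot(inherits(anterior, "spot_track"), inherits(posterior, "spot_track"))
  a <- anterior$samples; p <- posterior$samples
  key_a <- round(a$t, 9L); key_p <- round(p$t, 9L)
  common <- intersect(key_a, key_p)
  if (length(common) == 0L) stop("the two tracks share no timepoint")
  common <- sort(common)
  ia <- match(common, key_a); ip <- match(common, key_p)
  d <- sqrt((a$x[ia] - p$x[ip])^2 + (a$y[ia] - p$y[ip])^2)
  if (is.null(sampling_interval)) {
    steps <- c(diff(a$t), diff(p$t))
    sampling_interval <- min(steps[steps > 0])
  }
  distance_series(common, d, sampling_interval)
}

#' Double sliding-average smoothing of a distance series
#'
#' Each pass replaces `d(t)` by the unweighted mean of the samples of the same
#' contiguous run lying within the centred time window
#' `[t - window/2, t + window/2]`; near run edges the window truncates
#' (shrinks) rather than inventing data, and no window ever reaches across a
#' gap. Two consecutive 20-min passes — the default — isolate the long-scale
#' constriction activity from frame-to-frame jitter; on interior samples of a
#' uniformly sampled run this equals a single convolution with the
#' self-convolved (triangular) kernel of the boxcar.
#'
#' @param series a [distance_series()].
#' @param window window width in minutes (>= the sampling interval).
#' @param passes number of passes (default 2).
#' @return smoothed [distance_series()].
#' @export
smooth_distance <- function(series, window = 20, passes = 2) {
  stopifnot(inherits(series, "distance_series"))
  if (nrow(series) == 0L) stop("empty series")
  interval <- attr(series, "sampling_interval")
  if (window < interval) stop("window must be at least the sampling interval")
  t <- series$t; d <- series$d
  runs <- .series_runs(t, interval)
  for (pass in seq_len(passes)) {
    d_new <- d
    for (run in runs) {
      tr <- t[run]; dr <- d[run]
      for (i in seq_along(run)) {
        sel <- abs(tr - tr[i]) <= window / 2 + 1e-9
        d_new[run[i]] <- mean(dr[sel])
      }
    }
    d <- d_new
  }
  distance_series(t, pmax(d, 0), interval)
}

#' Closing-speed series
#'
#' `(t, v)` with `v` in um/min; closing (distance decreasing) is positive —
#' so slow-downs of the constriction appear as local minima of `v`.
#'
#' @param t,v numeric vectors.
#' @param sampling_interval minutes.
#' @return object of class `speed_series`.
#' @export
speed_series <- function(t, v, sampling_interval) {
  stopifnot(length(t) == length(v))
  if (any(diff(t) <= 0)) stop("timepoints must be strictly increasing")
  structure(data.frame(t = as.numeric(t), v = as.numeric(v)),
            sampling_interval = sampling_interval,
            class = c("speed_series", "data.frame"))
}

#' Differentiate the smoothed distance into a closing speed
#'
#' Central difference `v(t) = -(d(t+s) - d(t-s)) / (2s)` on the interior of
#' each contiguous run, one-sided differences at run edges; runs shorter than
#' 3 samples are dropped (an error if nothing remains). The minus sign makes
#' closing positive.
#'
#' @param smoothed a (smoothed) [distance_series()].
#' @return a [speed_series()].
#' @export
closing_speed <- function(smoothed) {
  stopifnot(inherits(smoothed, "distance_series"))
  interval <- attr(smoothed, "sampling_interval")
  runs <- .series_runs(smoothed$t, interval)
  runs <- runs[vapply(runs, length, integer(1L)) >= 3L]
  if (length(runs) == 0L) stop("no contiguous run of at least 3 samples")
  tt <- numeric(0); vv <- numeric(0)
  for (run in runs) {
    tr <- smoothed$t[run]; dr <- smoothed$d[run]
    n <- length(run)
    v <- numeric(n)
    v[1L] <- -(dr[2L] - dr[1L]) / (tr[2L] - tr[1L])
    v[n] <- -(dr[n] - dr[n - 1L]) / (tr[n] - tr[n - 1L])
    if (n > 2L) {
      i <- 2:(n - 1L)
      v[i] <- -(dr[i + 1L] - dr[i - 1L]) / (tr[i + 1L] - tr[i - 1L])
    }
    tt <- c(tt, tr); vv <- c(vv, v)
  }
  speed_series(tt, vv, interval)
}

# interior local minima of one run, plateaus resolved to their first sample;
# returns indices into v
.run_minima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  mins <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] < v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[i]) j <- j + 1L
      if (j < n && v[j + 1L] > v[i]) mins <- c(mins, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  mins
}

# topographic prominence of the minimum at index i of run v: on each side,
# walk until a strictly lower value (or the run end) and take the highest
# value passed; prominence = min(left peak, right peak) - v[i]
.run_prominence <- function(v, i) {
  m <- v[i]
  left <- v[seq_len(i - 1L)]
  lower_l <- which(left < m)
  lmax <- if (length(lower_l) > 0L) {
    max(left[(max(lower_l) + 1L):(i - 1L)])
  } else {
    max(left)
  }
  right <- v[(i + 1L):length(v)]
  lower_r <- which(right < m)
  rmax <- if (length(lower_r) > 0L) {
    max(right[seq_len(min(lower_r) - 1L)])
  } else {
    max(right)
  }
  min(lmax, rmax) - m
}

#' Prominence-filtered local minima of the closing speed
#'
#' Interior local minima of each contiguous run (strictly lower than both
#' neighbours; a flat plateau flanked by higher values counts once, at its
#' first sample; minima at run edges are excluded) retained when their
#' topographic prominence exceeds `prominence_threshold`. Prominence is the
#' depth of the minimum below the lower of the two highest values separating
#' it from the nearest deeper minimum (or the run end) on either side — the
#' standard definition used for filtering noisy local extrema.
#'
#' @param speed a [speed_series()].
#' @param prominence_threshold um/min (default 0.01); retained minima must
#'   exceed it strictly.
#' @return numeric vector of minima times (minutes), possibly empty, sorted,
#'   with an integer attribute `run_id` marking which contiguous run each
#'   minimum belongs to (consumed by [summarize_cycles()] so that no cycle
#'   duration is ever measured across a gap).
#' @export
find_cycle_minima <- function(speed, prominence_threshold = 0.01) {
  stopifnot(inherits(speed, "speed_series"), prominence_threshold > 0)
  interval <- attr(speed, "sampling_interval")
  runs <- .series_runs(speed$t, interval)
  times <- numeric(0)
  run_id <- integer(0)
  for (ri in seq_along(runs)) {
    run <- runs[[ri]]
    v <- speed$v[run]
    for (i in .run_minima(v)) {
      if (.run_prominence(v, i) > prominence_threshold) {
        times <- c(times, speed$t[run[i]])
        run_id <- c(run_id, ri)
      }
    }
  }
  o <- order(times)
  structure(times[o], run_id = run_id[o])
}

#' Summarise acceleration-deceleration cycles
#'
#' Cycle durations are the differences between successive retained
#' closing-speed minima; their mean and SEM estimate the oscillation period.
#' When the minima carry a `run_id` attribute (as returned by
#' [find_cycle_minima()]) only pairs of minima belonging to the same
#' contiguous run contribute a duration: an interval straddling a signal gap
#' may have skipped minima inside the gap and is not a measured cycle. Fewer
#' than two (pairable) minima yield an empty duration set and an `NA` mean.
#'
#' @param minima_times from [find_cycle_minima()]; a plain numeric vector is
#'   treated as one gap-free run.
#' @param prominence_threshold,window recorded for provenance.
#' @param passes number of smoothing passes used upstream.
#' @return object of class `oscillation_summary`: list with `minima_times`,
#'   `cycle_durations`, `mean_period`, `sem_period`, `n_cycles` and the
#'   recorded parameters.
#' @export
summarize_cycles <- function(minima_times, prominence_threshold = 0.01,
                             window = 20, passes = 2) {
  run_id <- attr(minima_times, "run_id")
  o <- order(minima_times)
  minima_times <- as.numeric(minima_times)[o]
  durations <- diff(minima_times)
  if (!is.null(run_id) && length(durations) > 0L) {
    run_id <- run_id[o]
    durations <- durations[run_id[-1L] == run_id[-length(run_id)]]
  }
  n <- length(durations)
  structure(
    list(
      minima_times = minima_times,
      cycle_durations = durations,
      n_cycles = n,
      mean_period = if (n >= 1L) mean(durations) else NA_real_,
      sem_period = if (n >= 2L) stats::sd(durations) / sqrt(n) else
        if (n == 1L) 0 else NA_real_,
      prominence_threshold = prominence_threshold,
      window = window,
      passes = passes
    ),
    class = "oscillation_summary"
  )
}

#' @export
print.oscillation_summary <- function(x, ...) {
  if (x$n_cycles == 0L) {
    cat("<oscillation_summary> no complete cycle detected\n")
  } else {
    cat(sprintf(
      "<oscillation_summary> %d cycle(s), period %.1f +/- %.1f min (mean +/- SEM)\n",
      x$n_cycles, x$mean_period, x$sem_period
    ))
  }
  invisible(x)
}

#' Track span along the tube axis
#'
#' Distance in x between the most anterior and most posterior positions
#' visited by a track.
#'
#' @param track a [spot_track()].
#' @return span in micrometres (0 for a single point).
#' @export
track_span <- function(track) {
  stopifnot(inherits(track, "spot_track"))
  max(track$samples$x) - min(track$samples$x)
}

#' Full kinetics pipeline for one anterior/posterior track pair
#'
#' [pair_distance()] -> [smooth_distance()] -> [closing_speed()] ->
#' [find_cycle_minima()] -> [summarize_cycles()].
#'
#' @param anterior,posterior [spot_track()]s.
#' @param window,passes smoothing parameters (minutes / count).
#' @param prominence_threshold um/min.
#' @param sampling_interval minutes (default: inferred).
#' @return list with `distance`, `smoothed`, `speed`, `minima`, `summary`.
#' @export
constriction_kinetics <- function(anterior, posterior, window = 20,
                                  passes = 2, prominence_threshold = 0.01,
                                  sampling_interval = NULL) {
  ds <- pair_distance(anterior, posterior, sampling_interval)
  sm <- smooth_distance(ds, window = window, passes = passes)
  sp <- closing_speed(sm)
  mins <- find_cycle_minima(sp, prominence_threshold)
  list(
    distance = ds, smoothed = sm, speed = sp, minima = mins,
    summary = summarize_cycles(mins, prominence_threshold, window, passes)
  )
}
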