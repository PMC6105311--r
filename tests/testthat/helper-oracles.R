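# Independent brute-force oracles. Everything here is written as plain
# per-pixel / per-sample loops against the definitions, deliberately sharing
# no code with the package internals.

# crown objective: classify every pixel by its Euclidean distance to the
# centre (pixel (i, j) sits at x = j-1, y = i-1)
oracle_crown_objective <- function(slice, cx, cy, r, w, lambda = 1,
                                   normalize = TRUE) {
  s_crown <- 0; n_crown <- 0L
  s_inner <- 0; n_inner <- 0L
  for (i in seq_len(nrow(slice))) {
    for (j in seq_len(ncol(slice))) {
      d <- sqrt((j - 1 - cx)^2 + (i - 1 - cy)^2)
      if (d >= r - w / 2 && d <= r + w / 2) {
        s_crown <- s_crown + slice[i, j]; n_crown <- n_crown + 1L
      } else if (d < r - w / 2) {
        s_inner <- s_inner + slice[i, j]; n_inner <- n_inner + 1L
      }
    }
  }
  if (normalize) {
    s_crown / n_crown -
      lambda * (if (n_inner > 0L) s_inner / n_inner else 0)
  } else {
    s_crown - lambda * s_inner
  }
}

# sector max: per angular bin (bin k centred at origin + k * 2pi/n), max over
# crown pixels whose angle falls in the bin
oracle_sector_max <- function(slice, cx, cy, r, w, n_theta, origin = 0) {
  out <- rep(-Inf, n_theta)
  dth <- 2 * pi / n_theta
  for (i in seq_len(nrow(slice))) {
    for (j in seq_len(ncol(slice))) {
      d <- sqrt((j - 1 - cx)^2 + (i - 1 - cy)^2)
      if (d >= r - w / 2 && d <= r + w / 2) {
        th <- atan2(i - 1 - cy, j - 1 - cx)
        k <- round((th - origin) / dth) %% n_theta
        out[k + 1] <- max(out[k + 1], slice[i, j])
      }
    }
  }
  out
}

# two-pass boxcar == one convolution with the self-convolved (triangular)
# kernel, valid where both passes saw a full window (uniform sampling)
oracle_double_boxcar <- function(d, m) {
  k <- 2 * m + 1
  box <- rep(1 / k, k)
  tri <- convolve(box, rev(box), type = "open")  # length 4m + 1
  n <- length(d)
  out <- rep(NA_real_, n)
  if (n >= 4 * m + 1) {
    for (i in (2 * m + 1):(n - 2 * m)) {
      out[i] <- sum(d[(i - 2 * m):(i + 2 * m)] * tri)
    }
  }
  out
}

# interior local minima (strictly below both flanks, plateau counted once at
# its first sample) with exhaustive-saddle prominence
oracle_prominent_minima <- function(v, thr) {
  n <- length(v)
  idx <- integer(0)
  for (i in 2:(n - 1)) {
    if (!(v[i] < v[i - 1])) next
    j <- i
    while (j < n && v[j + 1] == v[i]) j <- j + 1
    if (j >= n || v[j + 1] <= v[i]) next
    # prominence: highest point crossed before reaching lower ground
    lower_left <- which(v[1:(i - 1)] < v[i])
    saddle_l <- if (length(lower_left)) {
      max(v[(max(lower_left) + 1):(i - 1)])
    } else {
      max(v[1:(i - 1)])
    }
    right <- v[(i + 1):n]
    lower_right <- which(right < v[i])
    saddle_r <- if (length(lower_right)) {
      max(right[1:(min(lower_right) - 1)])
    } else {
      max(right)
    }
    if (min(saddle_l, saddle_r) - v[i] > thr) idx <- c(idx, i)
  }
  idx
}

# Delaunay adjacency of seeds on the unrolled cylinder (wrap in u), via
# deldir on three periodic copies
oracle_delaunay_adjacency <- function(u, z, circumference) {
  n <- length(u)
  dd <- deldir::deldir(
    c(u - circumference, u, u + circumference), rep(z, 3),
    rw = c(-circumference, 2 * circumference,
           min(z) - diff(range(z)) - 1, max(z) + diff(range(z)) + 1)
  )
  adj <- matrix(FALSE, n, n)
  central <- (n + 1):(2 * n)
  sg <- dd$delsgs
  for (e in seq_len(nrow(sg))) {
    i <- sg$ind1[e]; j <- sg$ind2[e]
    if (i %in% central || j %in% central) {
      bi <- (i - 1) %% n + 1
      bj <- (j - 1) %% n + 1
      if (bi != bj) adj[bi, bj] <- adj[bj, bi] <- TRUE
    }
  }
  adj
}

# vectorised point-in-polygon (ray crossing), for the Monte-Carlo area oracle
oracle_points_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- xy[i, 1]; yi <- xy[i, 2]
    xj <- xy[j, 1]; yj <- xy[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# quick constructors used across test files -----------------------------------

make_annulus_slice <- function(ny, nx, cx, cy, r, w, value = 100) {
  img <- matrix(0, ny, nx)
  for (i in seq_len(ny)) {
    for (j in seq_len(nx)) {
      d <- sqrt((j - 1 - cx)^2 + (i - 1 - cy)^2)
      if (abs(d - r) <= w / 2) img[i, j] <- value
    }
  }
  img
}

make_cylinder_volume <- function(nz, ny, nx, cx, cy, r, w = 3, value = 100,
                                 spacing = c(0.6, 0.2, 0.2)) {
  vox <- array(0, dim = c(nz, ny, nx))
  sl <- make_annulus_slice(ny, nx, cx, cy, r, w, value)
  for (z in seq_len(nz)) vox[z, , ] <- sl
  volume(vox, spacing)
}

# octagonal contour with an exact bounding box (width W along x, length L
# along y), anchored at (x0, y0)
octagon_contour <- function(x0, y0, W, L) {
  cbind(
    x = x0 + W * c(0, 0, 0.3, 0.7, 1, 1, 0.7, 0.3),
    y = y0 + L * c(0.3, 0.7, 1, 1, 0.7, 0.3, 0, 0)
  )
}

# synthetic stand-in for the deposited per-cell morphometry table: per-cell
# length/width planted so that each group's mean and SEM equal the printed
# values exactly (deterministic zero-mean unit-sd pattern, no RNG)
synthetic_cell_table <- function(n_per_group = 8) {
  e <- as.numeric(scale(seq_len(n_per_group)))  # mean 0, sample sd 1
  groups <- list(
    EHT = list(len = c(15.7, 1.6), wid = c(17.0, 0.9)),
    hemogenic = list(len = c(57.4, 5.2), wid = c(23.2, 2.5)),
    endothelial = list(len = c(57.7, 2.5), wid = c(43.6, 2.6))
  )
  rows <- lapply(names(groups), function(g) {
    p <- groups[[g]]
    data.frame(
      group = g,
      length_um = p$len[1] + p$len[2] * sqrt(n_per_group) * e,
      width_um = p$wid[1] + p$wid[2] * sqrt(n_per_group) * e
    )
  })
  do.call(rbind, rows)
}
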