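test_that("sample_ring matches the sector-max oracle on random slices", {
  set.seed(31)
  for (rep in 1:25) {
    slice <- matrix(runif(28 * 28, 0, 100), 28, 28)
    cx <- runif(1, 12.5, 14.5); cy <- runif(1, 12.5, 14.5)
    r <- runif(1, 7, 9); w <- 3
    n_theta <- sample(c(16L, 24L, 32L), 1)
    origin <- runif(1, -pi, pi)
    got <- sample_ring(slice, crown_circle(cx, cy, r, w), n_theta,
                       theta_origin = origin)
    want <- oracle_sector_max(slice, cx, cy, r, w, n_theta, origin)
    expect_identical(got, want)
  }
})

test_that("sample_ring constant field and delta response", {
  flat <- matrix(4.5, 40, 40)
  prof <- sample_ring(flat, crown_circle(20, 20, 10), 32)
  expect_equal(prof, rep(4.5, 32))

  # one bright pixel on the circle at theta = pi/2 lights exactly one bin
  img <- matrix(0, 40, 40)
  img[20 + 10 + 1, 20 + 1] <- 100   # (x, y) = (20, 30), straight "up"
  prof <- sample_ring(img, crown_circle(20, 20, 10), 32)
  hot <- which(prof > 0)
  expect_length(hot, 1L)
  expect_equal(hot - 1L, round((pi / 2) / (2 * pi / 32)))

  # crown fully outside the domain errors
  expect_error(sample_ring(matrix(0, 16, 16), crown_circle(40, 40, 6), 16),
               "no in-domain sample")
})

test_that("unwrap_volume geometry: dimensions, stripe, isotropy", {
  nz <- 12; r <- 25; dxy <- 0.2; dz <- 0.6
  rbar_um <- r * dxy
  N <- round(2 * pi * rbar_um / dz)

  truth <- data.frame(z = 0:(nz - 1), cx = 32, cy = 32, r = r,
                      score = 1, flagged = FALSE)
  tube <- tube_model(truth, c(dz, dxy, dxy), crown_width = 3)

  # longitudinal stripe at theta0: one near-vertical line in every row
  theta0 <- 1.1
  vox <- array(0, dim = c(nz, 64, 64))
  for (z in seq_len(nz)) {
    img <- matrix(0, 64, 64)
    for (i in 1:64) for (j in 1:64) {
      d <- sqrt((j - 1 - 32)^2 + (i - 1 - 32)^2)
      th <- atan2(i - 1 - 32, j - 1 - 32) %% (2 * pi)
      if (abs(d - r) <= 1.5 && abs(th - theta0) < 0.06) img[i, j] <- 100
    }
    vox[z, , ] <- img
  }
  map <- unwrap_volume(volume(vox, c(dz, dxy, dxy)), tube)
  expect_equal(dim(map$pixels), c(nz, N))         # dimension contract
  expect_equal(map$pixel_size, dz)
  expect_equal(map$row_radius, rep(rbar_um, nz))
  x_expect <- rbar_um * theta0 / dz
  for (row in seq_len(nz)) {
    hot <- which(map$pixels[row, ] > 50) - 1L
    expect_gt(length(hot), 0)
    expect_lte(diff(range(hot)), 2)               # lateral spread <= 2 px
    expect_lte(min(abs(hot - x_expect)), 2)       # position within 2 px
  }

  # square surface patch (side s um) maps to ~s/pixel_size px per side
  s <- 3
  u0 <- 8; z0_um <- 2.4
  vox2 <- array(0, dim = c(nz, 64, 64))
  for (z in seq_len(nz)) {
    zum <- (z - 1) * dz
    if (zum < z0_um || zum > z0_um + s) next
    img <- matrix(0, 64, 64)
    for (i in 1:64) for (j in 1:64) {
      d <- sqrt((j - 1 - 32)^2 + (i - 1 - 32)^2)
      u <- (atan2(i - 1 - 32, j - 1 - 32) %% (2 * pi)) * rbar_um
      if (abs(d - r) <= 1.5 && u >= u0 && u <= u0 + s) img[i, j] <- 100
    }
    vox2[z, , ] <- img
  }
  map2 <- unwrap_volume(volume(vox2, c(dz, dxy, dxy)), tube)
  bright <- map2$pixels > 50
  n_rows <- sum(rowSums(bright) > 0)
  n_cols_per_row <- rowSums(bright)[rowSums(bright) > 0]
  side_px <- s / dz
  expect_lte(abs(n_rows - side_px), 1)
  expect_true(all(abs(n_cols_per_row - side_px) <= 1))
})

test_that("theta-origin shift by whole bins cyclically shifts columns", {
  ph <- make_tube_phantom(tube_phantom_spec(
    n_slices = 8, image_size = c(64, 64), radius = 24, n_cells = 6, seed = 5
  ))
  truth <- ph$truth$centerline
  circles <- data.frame(z = truth$z, cx = truth$cx, cy = truth$cy,
                        r = ph$truth$radius_px, score = 1, flagged = FALSE)
  tube <- tube_model(circles, ph$volume$spacing, crown_width = 3)
  map0 <- unwrap_volume(ph$volume, tube)
  N <- ncol(map0$pixels)
  m <- 7L
  delta <- m * 2 * pi / N
  map1 <- unwrap_volume(ph$volume, tube, theta_origin = delta)
  shifted <- map0$pixels[, ((seq_len(N) - 1L + m) %% N) + 1L]
  expect_equal(map1$pixels, shifted)
  # the advertised column shift equals round(rbar * delta / pixel_size)
  expect_equal(m, round(tube$reference_radius * delta / map0$pixel_size))
})

test_that("duplicate_map copies columns, doubles intensity, refuses twice", {
  set.seed(32)
  map <- unwrapped_map(matrix(runif(10 * 120), 10, 120), pixel_size = 0.6)
  dup <- duplicate_map(map)
  expect_equal(ncol(dup$pixels), 240)
  expect_identical(dup$pixels[, 1:120], map$pixels)
  expect_identical(dup$pixels[, 121:240], map$pixels)
  expect_identical(sum(dup$pixels), 2 * sum(map$pixels))
  expect_true(dup$duplicated)
  expect_error(duplicate_map(dup), "already duplicated")
})

test_that("phantom ground-truth borders project onto map ridges", {
  ph <- make_tube_phantom(tube_phantom_spec(
    n_slices = 16, image_size = c(72, 72), radius = 28, n_cells = 8,
    interior_fraction = 0.3, seed = 6
  ))
  tube <- propagate_fit(ph$volume, crown_circle(35.5, 35.5, 28))
  map <- unwrap_volume(ph$volume, tube)
  px <- map$pixel_size
  C_um <- ph$truth$circumference_um
  L_um <- (16 - 1) * ph$volume$spacing[1]
  interior_level <- 0.3 * 100
  # sample points along ground-truth Voronoi border segments and map them
  # through the analytic (u, z) -> (X, Y) transform; the map there must be
  # brighter than cell-interior level (borders are painted brighter)
  sg <- ph$truth$borders
  hits <- 0L; total <- 0L
  for (e in seq_len(nrow(sg))) {
    for (f in c(0.25, 0.5, 0.75)) {
      u <- (sg$x1[e] + f * (sg$x2[e] - sg$x1[e])) %% C_um
      zum <- sg$y1[e] + f * (sg$y2[e] - sg$y1[e])
      if (zum < 0 || zum > L_um) next
      col <- round(u / px) %% ncol(map$pixels) + 1L
      row <- round(zum / ph$volume$spacing[1]) + 1L
      total <- total + 1L
      # allow 1 px of slack around the projected position
      cols <- (col + c(-1L, 0L, 1L) - 1L) %% ncol(map$pixels) + 1L
      rows <- pmax(1L, pmin(nrow(map$pixels), row + c(-1L, 0L, 1L)))
      if (max(map$pixels[rows, cols]) > interior_level * 1.5) hits <- hits + 1L
    }
  }
  expect_gt(total, 20)
  expect_gte(hits / total, 0.95)
})

test_that("unwrap_timelapse: stationarity, common width, shrinking radius", {
  vol <- make_cylinder_volume(6, 56, 56, 28, 28, 20)
  res <- unwrap_timelapse(list(vol, vol, vol), crown_circle(28, 28, 20))
  expect_length(res$maps, 3L)
  expect_identical(res$maps[[1]]$pixels, res$maps[[2]]$pixels)
  expect_identical(res$maps[[2]]$pixels, res$maps[[3]]$pixels)

  # radius shrinking ~2 % per frame: fitted rbar decreases, width constant
  radii <- c(24, 23.5, 23, 22.5)
  frames <- lapply(radii, function(r) {
    make_cylinder_volume(6, 64, 64, 32, 32, r)
  })
  res2 <- unwrap_timelapse(frames, crown_circle(32, 32, 24), step = 0.5)
  rbars <- vapply(res2$tubes, function(tb) tb$reference_radius, numeric(1))
  expect_true(all(diff(rbars) < 0))
  widths <- vapply(res2$maps, function(m) ncol(m$pixels), numeric(1))
  expect_equal(widths, rep(widths[1], 4))
})

test_that("maps serialize with sidecar metadata", {
  set.seed(33)
  map <- unwrapped_map(matrix(runif(6 * 40), 6, 40), pixel_size = 0.6,
                       row_radius = rep(5, 6))
  f <- withr::local_tempfile(fileext = ".tif")
  write_map(map, f)
  back <- aortamap:::read_tiff(f)
  expect_equal(back$pixels[1, , ], map$pixels, tolerance = 1e-7)
  meta <- read.csv(paste0(f, ".meta.csv"))
  expect_equal(meta$pixel_size[1], 0.6)
  expect_equal(meta$row_radius, rep(5, 6))
  expect_false(any(meta$duplicated))
})
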