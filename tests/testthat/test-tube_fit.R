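test_that("crown_objective matches the per-pixel classification oracle", {
  set.seed(21)
  for (rep in 1:25) {
    slice <- matrix(runif(24 * 24, 0, 100), 24, 24)
    cx <- runif(1, 10, 13); cy <- runif(1, 10, 13)
    r <- runif(1, 5, 8); w <- sample(2:4, 1)
    lambda <- runif(1, 0.5, 2)
    cc <- crown_circle(cx, cy, r, w)
    expect_equal(
      crown_objective(slice, cc, lambda = lambda),
      oracle_crown_objective(slice, cx, cy, r, w, lambda = lambda),
      tolerance = 1e-12
    )
    expect_equal(
      crown_objective(slice, cc, lambda = lambda, normalize = FALSE),
      oracle_crown_objective(slice, cx, cy, r, w, lambda = lambda,
                             normalize = FALSE),
      tolerance = 1e-12
    )
  }
})

test_that("crown_objective degenerate and constructed cases", {
  zero <- matrix(0, 32, 32)
  cc <- crown_circle(16, 16, 8)
  expect_equal(crown_objective(zero, cc), 0)

  ann <- make_annulus_slice(40, 40, 20, 20, 10, 3)
  at <- crown_objective(ann, crown_circle(20, 20, 10, 3))
  for (dr in c(-4, 4, 5)) {
    expect_gt(at, crown_objective(ann, crown_circle(20, 20, 10 + dr, 3)))
  }
  expect_error(crown_objective(ann, crown_circle(2, 20, 10, 3)), "domain")
})

test_that("fit_circle_slice equals the exhaustive oracle and recovers optima", {
  # noiseless annulus, init offset by (2, -2, +1)
  ann <- make_annulus_slice(32, 32, 16, 16, 10, 3)
  fit <- fit_circle_slice(ann, crown_circle(18, 14, 11, 3))
  expect_lte(abs(fit$cx - 16), 0.5)
  expect_lte(abs(fit$cy - 16), 0.5)
  expect_lte(abs(fit$r - 10), 0.5)

  # flat objective: tie-break returns the init unchanged
  flat <- matrix(7, 32, 32)
  fit0 <- fit_circle_slice(flat, crown_circle(15, 17, 9, 3))
  expect_equal(c(fit0$cx, fit0$cy, fit0$r), c(15, 17, 9))

  # random slices: argmax equals exhaustive enumeration with the same
  # tie-break, and never scores below the initialization
  set.seed(22)
  for (rep in 1:3) {
    slice <- matrix(runif(26 * 26, 0, 50), 26, 26)
    init <- crown_circle(12.5, 12.5, 7, 3)
    fit <- fit_circle_slice(slice, init)
    best <- NULL
    for (dcx in -3:3) for (dcy in -3:3) for (dr in -3:3) {
      cx <- init$cx + dcx; cy <- init$cy + dcy; r <- init$r + dr
      if (r - 1.5 <= 0) next
      if (cx - r - 1.5 < 0 || cx + r + 1.5 > 25) next
      if (cy - r - 1.5 < 0 || cy + r + 1.5 > 25) next
      sc <- oracle_crown_objective(slice, cx, cy, r, 3)
      d0 <- dcx^2 + dcy^2 + dr^2
      if (is.null(best) || sc > best$sc ||
          (sc == best$sc && d0 < best$d0)) {
        best <- list(cx = cx, cy = cy, r = r, sc = sc, d0 = d0)
      }
    }
    expect_equal(c(fit$cx, fit$cy, fit$r), c(best$cx, best$cy, best$r))
    expect_gte(fit$score, crown_objective(slice, init))
  }
})

test_that("propagate_fit follows the tube and flags dropouts", {
  # constant-radius straight phantom: exact recovery
  vol <- make_cylinder_volume(8, 40, 40, 20, 20, 12)
  tube <- propagate_fit(vol, crown_circle(21, 19, 13))
  expect_true(all(abs(tube$circles$cx - 20) <= 0.5))
  expect_true(all(abs(tube$circles$cy - 20) <= 0.5))
  expect_true(all(abs(tube$circles$r - 12) <= 0.5))
  expect_equal(tube$reference_radius, 12 * 0.2)
  expect_false(any(tube$circles$flagged))
  # axis in um, z strictly increasing
  expect_equal(tube$axis[, "z"], (0:7) * 0.6)

  # linear centre drift 0.2 px/slice: per-slice error <= 1 px
  nz <- 12
  vox <- array(0, dim = c(nz, 40, 40))
  for (z in seq_len(nz)) {
    vox[z, , ] <- make_annulus_slice(40, 40, 18 + 0.2 * (z - 1), 20, 10, 3)
  }
  vdrift <- volume(vox, c(0.6, 0.2, 0.2))
  tube2 <- propagate_fit(vdrift, crown_circle(18, 20, 10))
  truth_cx <- 18 + 0.2 * (0:(nz - 1))
  expect_true(all(abs(tube2$circles$cx - truth_cx) <= 1))
  expect_true(all(abs(tube2$circles$cy - 20) <= 1))

  # an all-zero middle slice is carried over and flagged
  vox3 <- vol$voxels
  vox3[4, , ] <- 0
  v3 <- volume(vox3, vol$spacing)
  tube3 <- propagate_fit(v3, crown_circle(20, 20, 12), quality_floor = 1)
  expect_true(tube3$circles$flagged[4])
  expect_equal(unlist(tube3$circles[4, c("cx", "cy", "r")]),
               unlist(tube3$circles[3, c("cx", "cy", "r")]),
               ignore_attr = TRUE)
  expect_false(any(tube3$circles$flagged[-4]))

  # first slice below the floor is an error
  vz <- volume(array(0, dim = c(3, 40, 40)), c(0.6, 0.2, 0.2))
  expect_error(propagate_fit(vz, crown_circle(20, 20, 12), quality_floor = 1),
               "first slice")
})

test_that("radius continuity bound holds on a tapering phantom", {
  nz <- 10
  vox <- array(0, dim = c(nz, 48, 48))
  for (z in seq_len(nz)) {
    vox[z, , ] <- make_annulus_slice(48, 48, 24, 24, 16 - 0.5 * (z - 1), 3)
  }
  tube <- propagate_fit(volume(vox, c(0.6, 0.2, 0.2)),
                        crown_circle(24, 24, 16), max_radius_step = 2)
  expect_true(all(abs(diff(tube$circles$r)) <= 2))
  expect_true(all(abs(tube$circles$r - (16 - 0.5 * (0:(nz - 1)))) <= 1))
})

test_that("fit with noise stays within 1 px (median over seeds)", {
  errs <- sapply(1:5, function(s) {
    set.seed(100 + s)
    sl <- make_annulus_slice(40, 40, 20, 20, 12, 3, value = 100) +
      matrix(rnorm(1600, sd = 10), 40, 40)
    sl[sl < 0] <- 0
    fit <- fit_circle_slice(sl, crown_circle(22, 18, 13))
    max(abs(c(fit$cx - 20, fit$cy - 20, fit$r - 12)))
  })
  expect_lte(median(errs), 1)
})

test_that("anisotropic in-plane spacing is rejected", {
  vox <- array(1, dim = c(3, 16, 16))
  v <- volume(vox, c(0.6, 0.2, 0.3))
  expect_error(propagate_fit(v, crown_circle(8, 8, 5)), "anisotropic")
})

test_that("tube model serializes to CSV and back", {
  vol <- make_cylinder_volume(4, 40, 40, 20, 20, 12)
  tube <- propagate_fit(vol, crown_circle(20, 20, 12))
  f <- withr::local_tempfile(fileext = ".csv")
  write_tube_csv(tube, f)
  back <- read_tube_csv(f)
  expect_equal(back$cx, tube$circles$cx)
  expect_equal(back$r, tube$circles$r)
  expect_equal(back$flagged, tube$circles$flagged)
})

test_that("reorient permutes axes and recovers a tube laid along y", {
  set.seed(23)
  vox <- array(runif(10 * 20 * 30), dim = c(10, 20, 30))
  v <- volume(vox, c(0.6, 0.3, 0.3))
  p <- reorient(v, "yzx")
  expect_equal(dim(p$voxels), c(20, 10, 30))
  expect_equal(p$spacing, c(0.3, 0.6, 0.3))
  expect_equal(p$voxels[3, 5, 7], v$voxels[5, 3, 7])
  expect_equal(reorient(v, "zyx")$voxels, v$voxels)   # identity

  # cylinder laid along y, reoriented, fitted: radius recovered
  tube_vol <- make_cylinder_volume(10, 40, 40, 20, 20, 12,
                                   spacing = c(0.2, 0.2, 0.2))
  laid <- volume(aperm(tube_vol$voxels, c(2, 1, 3)), c(0.2, 0.2, 0.2))
  fixed <- reorient(laid, "yzx")
  tube <- propagate_fit(fixed, crown_circle(21, 21, 13))
  expect_true(all(abs(tube$circles$r - 12) <= 0.5))
  expect_true(all(abs(tube$circles$cx - 20) <= 0.5))
})

test_that("reorient by rotation: zero angle is identity, small angle keeps data", {
  set.seed(24)
  vox <- array(runif(6 * 24 * 24), dim = c(6, 24, 24))
  v <- volume(vox, c(0.5, 0.5, 0.5))
  expect_equal(reorient(v, list(axis = "z", angle = 0))$voxels, v$voxels)
  rot <- reorient(v, list(axis = "z", angle = 5))
  expect_equal(dim(rot$voxels), dim(v$voxels))
  # centre voxel is fixed by an in-plane rotation about the grid centre
  expect_equal(rot$voxels[3, 12, 12], v$voxels[3, 12, 12])
})
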