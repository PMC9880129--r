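test_that("default phantom follows the clinical acquisition protocol", {
  ph <- generate_phantom(phantom_config())
  expect_equal(ph$series$times, c(0, 90, 160, 230, 300, 370))
  expect_equal(dim(ph$series$voxels)[4], 6L)
  expect_equal(ph$series$spacing, c(0.7, 0.7, 2.0))
})

test_that("no enhancement and no motion yields identical volumes", {
  cfg <- small_phantom_config(
    lesion = list(center = c(8, 18, 5), radius_mm = 3.5,
                  ktrans = 0, ve = 0.3, vp = 0),
    background = list(
      list(center = c(8, 16, 5.5), semi_axes_mm = c(5, 9, 7),
           baseline = 100)),
    texture_amplitude = 0.1
  )
  ph <- generate_phantom(cfg)
  for (g in 2:6)
    expect_equal(ph$series$voxels[, , , g], ph$series$voxels[, , , 1],
                 tolerance = 0)
  expect_true(all(compute_subtractions(ph$series)$voxels == 0))
})

test_that("lesion voxel curves equal the forward Tofts signal model", {
  cfg <- phantom_config()
  ph <- generate_phantom(cfg)
  ct <- tofts_concentration(cfg$times,
                            tofts_params(0.103, 0.3, 0.02), cfg$aif)
  mask <- ph$truth$lesion_mask
  idx <- which(mask, arr.ind = TRUE)
  for (k in c(1, nrow(idx) %/% 2, nrow(idx))) {
    v <- idx[k, ]
    curve <- ph$truth$clean_series$voxels[v[1], v[2], v[3], ]
    baseline <- curve[1] / (1 + ct[1])
    expect_equal(curve, baseline * (1 + ct), tolerance = 1e-12)
  }
  # and the no-motion no-noise series IS the clean series
  expect_identical(ph$series$voxels, ph$truth$clean_series$voxels)
})

test_that("phantom generation is deterministic and seed-sensitive", {
  cfg <- small_phantom_config(motion_mode = "bspline",
                              motion_amplitude = 3, noise_sigma = 0.02,
                              seed = 5)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$series$voxels, b$series$voxels)
  expect_identical(a$truth$motion$coefficients, b$truth$motion$coefficients)
  cfg2 <- small_phantom_config(motion_mode = "bspline",
                               motion_amplitude = 3, noise_sigma = 0.02,
                               seed = 6)
  c <- generate_phantom(cfg2)
  expect_false(identical(a$series$voxels, c$series$voxels))
})

test_that("lesion enhancement rises from injection with a decaying AIF", {
  cfg <- phantom_config(lesion = list(center = c(16, 36, 8),
                                      radius_mm = 5.6, ktrans = 0.103,
                                      ve = 0.3, vp = 0))
  ct <- tofts_concentration(cfg$times,
                            tofts_params(0.103, 0.3, 0), cfg$aif)
  expect_equal(ct[1], 0)
  expect_gt(ct[2], 0)
})

test_that("invalid configurations are rejected", {
  expect_error(phantom_config(lesion = list(center = c(2, 2, 2),
                                            radius_mm = 10, ktrans = 0.1,
                                            ve = 0.3, vp = 0.02)),
               "outside grid")
  expect_error(phantom_config(lesion = list(center = c(16, 36, 8),
                                            radius_mm = 5.6, ktrans = -1,
                                            ve = 0.3, vp = 0.02)),
               "ktrans")
  expect_error(phantom_config(motion_amplitude = -1), "motion_amplitude")
  expect_error(phantom_config(noise_sigma = -0.1), "noise_sigma")
})

test_that("injected motion is identity at the unenhanced timepoint and
           bounded by the configured amplitude", {
  cfg <- small_phantom_config(motion_mode = "bspline",
                              motion_amplitude = 4, seed = 2)
  ph <- generate_phantom(cfg)
  motion <- ph$truth$motion
  expect_true(all(motion$coefficients[, , , , 1] == 0))
  expect_equal(max(abs(motion$coefficients)), 4)
  # dense displacement evaluation: per-axis displacement cannot exceed the
  # coefficient bound (B-spline basis is a partition of unity)
  pts <- dcereg:::lattice_points(dim(ph$series$voxels)[1:3],
                                 cfg$spacing)
  for (g in 2:6) {
    u <- ffd_displacement(motion, pts, g)
    expect_lte(max(abs(u)), 4 + 1e-9)
  }
})

test_that("applying identity motion reproduces the series", {
  ph <- generate_phantom(small_phantom_config())
  ext <- (dim(ph$series$voxels)[1:3] - 1) * ph$series$spacing
  ident <- bspline_motion(ext, 16, 6)
  out <- apply_motion(ph$series, ident)
  expect_equal(out$voxels, ph$series$voxels, tolerance = 1e-12)
})

test_that("integer-voxel translation shifts a volume exactly (interior)", {
  ph <- generate_phantom(small_phantom_config())
  s <- ph$series
  ext <- (dim(s$voxels)[1:3] - 1) * s$spacing
  shifts <- matrix(0, 6, 3)
  shifts[4, ] <- c(2 * s$spacing[1], 0, 0)  # +2 voxels along x
  tm <- dcereg:::translation_model(ext, 16, shifts)
  out <- apply_motion(s, tm)
  d <- dim(s$voxels)[1:3]
  # out(x) = in(x + 2vox): interior voxels are exact copies
  expect_equal(out$voxels[1:(d[1] - 2), , , 4],
               s$voxels[3:d[1], , , 4], tolerance = 1e-9)
  expect_identical(out$voxels[, , , 1], s$voxels[, , , 1])
})

test_that("additive noise is seeded, reproducible and well-calibrated", {
  vol <- dce_series(array(100, c(40, 40, 40, 2)), c(1, 1, 1), c(0, 90))
  expect_identical(add_noise(vol, 0), vol)
  expect_error(add_noise(vol, -1), "sigma")
  a <- add_noise(vol, 5, seed = 42)
  b <- add_noise(vol, 5, seed = 42)
  expect_identical(a$voxels, b$voxels)
  expect_false(identical(a$voxels, add_noise(vol, 5, seed = 43)$voxels))
  expect_equal(sd(a$voxels - vol$voxels), 5, tolerance = 0.02)
  expect_equal(mean(a$voxels - vol$voxels), 0, tolerance = 0.05)
  # rician magnitude noise stays non-negative on a zero background
  z <- dce_series(array(0, c(10, 10, 10, 2)), c(1, 1, 1), c(0, 90))
  r <- add_noise(z, 5, seed = 1, model = "rician")
  expect_true(all(r$voxels >= 0))
})
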