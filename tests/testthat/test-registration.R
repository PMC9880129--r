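test_that("down-sampling halves dimensions, doubles spacing, and
           preserves constants exactly", {
  s <- dce_series(array(rnorm(64 * 64 * 16 * 2), c(64, 64, 16, 2)),
                  c(0.7, 0.7, 2), c(0, 90))
  expect_identical(downsample_series(s, 1), s)
  d2 <- downsample_series(s, 2)
  expect_equal(dim(d2$voxels), c(32L, 32L, 8L, 2L))
  expect_equal(d2$spacing, c(1.4, 1.4, 4))
  expect_error(downsample_series(s, 32), "exceeds")
  const <- dce_series(array(7, c(16, 16, 8, 2)), c(1, 1, 1), c(0, 90))
  for (f in c(2, 4))
    expect_equal(unique(as.vector(downsample_series(const, f)$voxels)), 7,
                 tolerance = 1e-12)
})

test_that("B-spline coefficient subdivision reproduces the displacement
           field at half control spacing", {
  ext <- c(30, 30, 20)
  model <- bspline_motion(ext, 8, 2)
  set.seed(5)
  model$coefficients[] <- rnorm(length(model$coefficients))
  fine <- dcereg:::subdivide_model(model, ext)
  expect_equal(fine$control_spacing, model$control_spacing / 2)
  pts <- cbind(runif(200, 2, ext[1] - 2), runif(200, 2, ext[2] - 2),
               runif(200, 2, ext[3] - 2))
  for (g in 1:2)
    expect_equal(ffd_displacement(fine, pts, g),
                 ffd_displacement(model, pts, g), tolerance = 1e-10)
})

test_that("motion model JSON transforms round-trip", {
  model <- bspline_motion(c(30, 30, 20), 8, 3)
  set.seed(6)
  model$coefficients[] <- rnorm(length(model$coefficients))
  path <- withr::local_tempfile(fileext = ".json")
  write_motion_model(model, path)
  m2 <- read_motion_model(path)
  expect_equal(m2$coefficients, model$coefficients)
  expect_equal(m2$control_spacing, model$control_spacing)
  expect_equal(m2$grid_dim, model$grid_dim)
})

test_that("resampling through the identity reproduces the image", {
  ph <- generate_phantom(small_phantom_config())
  ext <- (dim(ph$series$voxels)[1:3] - 1) * ph$series$spacing
  out <- resample_series(ph$series, bspline_motion(ext, 16, 6))
  expect_equal(out$voxels, ph$series$voxels, tolerance = 1e-12)
})

test_that("forward-inverse displacement round trip is small interiorly", {
  ph <- generate_phantom(small_phantom_config())
  s <- ph$series
  ext <- (dim(s$voxels)[1:3] - 1) * s$spacing
  model <- bspline_motion(ext, 12, 6)
  set.seed(7)
  model$coefficients[] <- rnorm(length(model$coefficients), sd = 0.4)
  inv <- model
  inv$coefficients <- -model$coefficients
  there <- resample_series(s, model)
  back <- resample_series(there, inv)
  d <- dim(s$voxels)[1:3]
  core <- list(5:(d[1] - 4), 5:(d[2] - 4), 2:(d[3] - 1))
  rng <- diff(range(s$voxels))
  err <- abs(back$voxels[core[[1]], core[[2]], core[[3]], ] -
             s$voxels[core[[1]], core[[2]], core[[3]], ])
  expect_lt(mean(err) / rng, 0.01)
})

test_that("resampling a corrupted phantom with the inverted truth motion
           moves it back toward the clean series", {
  cfg <- small_phantom_config(motion_mode = "bspline",
                              motion_amplitude = 3, seed = 9)
  ph <- generate_phantom(cfg)
  inv <- ph$truth$motion
  inv$coefficients <- -inv$coefficients
  restored <- resample_series(ph$series, inv)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  clean <- ph$truth$clean_series$voxels
  expect_lt(rmse(restored$voxels, clean), rmse(ph$series$voxels, clean))
})

test_that("registration configuration validates its schedule", {
  expect_error(registration_config(pyramid = c(4, 8, 1)),
               "non-increasing")
  expect_error(registration_config(pyramid = c(4, 2)), "ending at 1")
  expect_error(registration_config(control_spacing = c(32, 16)),
               "one spacing per")
  expect_error(registration_config(control_spacing = c(32, 20, 8, 8)),
               "halve")
})

test_that("groupwise registration recovers a single translated volume and
           improves the metric", {
  cfg <- small_phantom_config()
  ph <- generate_phantom(cfg)
  s <- ph$series
  ext <- (dim(s$voxels)[1:3] - 1) * s$spacing
  shifts <- matrix(0, 6, 3)
  shifts[3, ] <- c(1.4, -1.4, 0)          # 2 voxels in-plane
  corrupted <- apply_motion(s, dcereg:::translation_model(ext, 16, shifts))
  rc <- registration_config(pyramid = c(4L, 2L, 1L),
                            control_spacing = c(16, 16, 8),
                            iterations_per_level = 150L,
                            n_samples = 1024L, seed = 1)
  reg <- register_groupwise(corrupted, rc)
  expect_lt(reg$metric_post, reg$metric_pre)
  # groupwise gauge: mean displacement over timepoints is zero
  mean_coef <- apply(reg$model$coefficients, 1:4, mean)
  expect_lt(max(abs(mean_coef)), 1e-10)
  # after rebasing to the unenhanced volume, the recovered displacement at
  # the shifted timepoint approximates the inverse shift over the breast
  model <- rebase_model(reg$model, 1)
  ph_for_pts <- list(truth = list(clean_series = ph$truth$clean_series))
  pts <- breast_points(ph_for_pts, thin = 11)
  u <- ffd_displacement(model, pts, 3)
  err <- sqrt(rowSums(sweep(u, 2, -shifts[3, ], `-`)^2))
  expect_lt(median(err), 0.5 * min(s$spacing))
})

test_that("registration refuses meaningless inputs", {
  s <- tiny_series(G = 2)
  expect_error(register_groupwise(s), "at least 3 timepoints")
  s3 <- tiny_series(G = 3)
  expect_error(register_groupwise(
    s3, registration_config(n_samples = 2L)), "n_samples")
})

test_that("registration is deterministic for a fixed seed", {
  cfg <- small_phantom_config(motion_mode = "rigid", motion_amplitude = 2,
                              seed = 3)
  ph <- generate_phantom(cfg)
  rc <- registration_config(pyramid = c(4L, 1L),
                            control_spacing = c(16, 16),
                            iterations_per_level = 40L,
                            n_samples = 512L, seed = 11)
  a <- register_groupwise(ph$series, rc)
  b <- register_groupwise(ph$series, rc)
  expect_identical(a$model$coefficients, b$model$coefficients)
  expect_equal(a$metric_post, b$metric_post)
})

test_that("deterministic finite-difference descent mode runs and does not
           degrade alignment", {
  set.seed(55)
  base <- array(0, c(6, 6, 4))
  base[2:5, 2:5, 2:3] <- 10
  base <- array(dcereg:::cpp_smooth_gaussian(as.numeric(base),
                                             c(6, 6, 4), c(1, 1, 0.7)),
                c(6, 6, 4))
  vox <- array(0, c(6, 6, 4, 3))
  for (g in 1:3) vox[, , , g] <- base * (1 + 0.1 * g)
  s <- dce_series(vox, c(1, 1, 1), c(0, 90, 160))
  ext <- (dim(vox)[1:3] - 1) * c(1, 1, 1)
  shifts <- matrix(0, 3, 3); shifts[2, 1] <- 0.8
  corrupted <- apply_motion(s, dcereg:::translation_model(ext, 8, shifts))
  rc <- registration_config(pyramid = c(1L), control_spacing = 8,
                            iterations_per_level = 4L, n_samples = 96L,
                            optimizer = "finite_difference_descent",
                            validation_samples = 256L, seed = 2)
  a <- register_groupwise(corrupted, rc)
  b <- register_groupwise(corrupted, rc)
  expect_identical(a$model$coefficients, b$model$coefficients)
  expect_lte(a$metric_post, a$metric_pre + 0.05)
})
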