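test_that("biexponential AIF evaluates to its closed form", {
  aif <- aif_weinmann()
  expect_equal(aif_value(aif, 0), 0.1 * (3.99 + 4.78))
  # direct scalar oracle at t = 90 s
  oracle <- 0.1 * (3.99 * exp(-0.144 * 1.5) + 4.78 * exp(-0.0111 * 1.5))
  expect_equal(aif_value(aif, 90), oracle, tolerance = 1e-12)
  expect_lt(aif_value(aif, 1e7), 1e-8)     # decays to zero
  expect_error(aif_value(aif, -1), "negative")
  # sampled AIFs interpolate linearly and vanish before the first sample
  sa <- aif_sampled(c(10, 20, 30), c(0, 1, 0.5))
  expect_equal(aif_value(sa, 15), 0.5)
  expect_equal(aif_value(sa, 5), 0)
})

test_that("extended Tofts limiting cases are exact", {
  times <- c(0, 90, 160, 230, 300, 370)
  aif <- aif_weinmann()
  expect_equal(tofts_concentration(times, tofts_params(0, 0.3, 0), aif),
               rep(0, 6))
  expect_equal(tofts_concentration(times, tofts_params(0, 0.3, 0.05), aif),
               0.05 * aif_value(aif, times), tolerance = 1e-14)
  expect_error(tofts_params(0.2, 0, 0.05), "k_ep")
  # linearity in vp: the partial derivative is exactly Cp(t)
  p1 <- tofts_concentration(times, tofts_params(0.1, 0.3, 0.02), aif)
  p2 <- tofts_concentration(times, tofts_params(0.1, 0.3, 0.07), aif)
  expect_equal((p2 - p1) / 0.05, aif_value(aif, times), tolerance = 1e-10)
})

test_that("closed-form convolution matches a fine-grid trapezoid oracle", {
  times <- c(0, 90, 160, 230, 300, 370)
  aif <- aif_weinmann()
  trapz_oracle <- function(p, dt = 0.05) {
    kep <- p$ktrans / p$ve
    sapply(times, function(t_i) {
      vp_term <- p$vp * aif_value(aif, t_i)
      if (t_i == 0) return(vp_term)
      grid <- seq(0, t_i, by = dt)
      f <- aif_value(aif, grid) * exp(-kep * (t_i - grid) / 60)
      vp_term + p$ktrans * sum(diff(grid) * (f[-length(f)] + f[-1]) / 2) / 60
    })
  }
  p <- tofts_params(0.103, 0.3, 0.02)
  cf <- tofts_concentration(times, p, aif)
  or <- trapz_oracle(p)
  expect_lt(max(abs(cf - or) / pmax(abs(or), 1e-12)), 1e-4)
  # and the sampled-AIF numerical path agrees with the closed form
  ts <- seq(0, 400, by = 0.5)
  sa <- aif_sampled(ts, aif_value(aif, ts))
  num <- tofts_concentration(times, p, sa, dt_s = 0.05)
  expect_lt(max(abs(num - cf)) / max(cf), 2e-3)
})

test_that("noiseless self-consistency: fitting a model-generated curve
           recovers the parameters", {
  times <- c(0, 90, 160, 230, 300, 370)
  truth <- tofts_params(0.2, 0.25, 0.03)
  curve <- tofts_rel_enhancement(times, truth)
  f <- fit_tofts_voxel(curve, times)
  expect_lt(abs(f$params$ktrans - 0.2) / 0.2, 0.01)
  expect_lt(abs(f$params$ve - 0.25) / 0.25, 0.01)
  expect_lt(abs(f$params$vp - 0.03) / 0.03, 0.01)
  expect_lt(f$residual, 1e-8)
})

test_that("degenerate fit inputs behave as specified", {
  times <- c(0, 90, 160, 230, 300, 370)
  z <- fit_tofts_voxel(rep(0, 6), times)
  expect_lt(z$params$ktrans, 0.01)
  expect_lt(z$residual, 1e-4)
  expect_error(fit_tofts_voxel(rep(NaN, 6), times), "NaN")
  expect_error(fit_tofts_voxel(c(0, 0.1, 0.2), c(0, 90, 160)),
               "at least 4")
})

test_that("ROI fitting recovers uniform truth and flags grid mismatch", {
  cfg <- small_phantom_config()
  ph <- generate_phantom(cfg)
  roi <- ph$truth$lesion_mask
  fit <- fit_tofts_roi(ph$series, roi)
  kt <- fit$ktrans[roi]
  expect_equal(mean(kt), 0.103, tolerance = 0.01)
  expect_lt(sd(kt) / mean(kt), 0.01)
  expect_true(all(is.nan(fit$ktrans[!roi])))
  expect_error(fit_tofts_roi(ph$series, roi[1:10, 1:10, , drop = FALSE]),
               "do not match")
  expect_error(fit_tofts_roi(ph$series, array(FALSE, dim(roi))),
               "empty ROI")
  # tidy/glance expose the voxel table and the summary
  td <- tidy(fit)
  expect_equal(nrow(td), sum(roi))
  expect_true(all(c("ktrans", "residual") %in% names(td)))
  expect_equal(glance(fit)$n_voxels, sum(roi))
})

test_that("a single-voxel ROI yields maps defined exactly there", {
  cfg <- small_phantom_config()
  ph <- generate_phantom(cfg)
  roi <- array(FALSE, dim(ph$series$voxels)[1:3])
  ctr <- cfg$lesion$center
  roi[ctr[1], ctr[2], ctr[3]] <- TRUE
  fit <- fit_tofts_roi(ph$series, roi)
  expect_false(is.nan(fit$ktrans[ctr[1], ctr[2], ctr[3]]))
  expect_equal(sum(!is.nan(fit$ktrans)), 1L)
})

test_that("residual percentiles follow the sort-and-interpolate oracle", {
  mask <- array(TRUE, c(10, 10, 1))
  resid <- array(as.numeric(1:100), c(10, 10, 1))
  out <- residual_percentiles(resid, mask, percentiles = c(10, 50, 90))
  # linear-interpolation convention on the sorted values
  expect_equal(out$value,
               as.numeric(quantile(1:100, c(0.1, 0.5, 0.9), type = 7)))
  expect_equal(out$value[2], 50.5)
  # constant distribution: every percentile equals the constant
  cst <- residual_percentiles(array(0.2, c(5, 5, 2)),
                              array(TRUE, c(5, 5, 2)))
  expect_true(all(cst$value == 0.2))
  # monotone in the percentile level
  set.seed(8)
  r <- array(rexp(250), c(5, 5, 10))
  v <- residual_percentiles(r, array(TRUE, c(5, 5, 10)))$value
  expect_true(all(diff(v) >= 0))
  expect_error(residual_percentiles(r, array(FALSE, c(5, 5, 10))),
               "empty ROI")
})
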