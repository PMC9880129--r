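test_that("every NRS value maps to its motion category", {
  expect_identical(nrs_to_category(0:10),
                   c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L, 3L))
  # total, monotone non-decreasing, surjective onto 0..3
  cats <- nrs_to_category(0:10)
  expect_true(all(diff(cats) >= 0))
  expect_setequal(unique(cats), 0:3)
  expect_error(nrs_to_category(11), "0..10")
  expect_error(nrs_to_category(-1), "0..10")
  expect_error(nrs_to_category(2.5), "0..10")
  ms <- motion_score(c(0, 4, 8))
  expect_equal(ms$category, c(0L, 2L, 3L))
})

make_fit <- function(resid_values, ktrans_values, dims = c(5, 5, 4)) {
  mask <- array(FALSE, dims)
  mask[seq_along(resid_values)] <- TRUE
  res <- array(NaN, dims); res[mask] <- resid_values
  kt <- array(NaN, dims); kt[mask] <- ktrans_values
  structure(
    list(ktrans = kt, ve = kt, vp = kt, residual = res, roi = mask,
         n_timepoints = 6L,
         summary = tibble::tibble(
           n_voxels = length(resid_values),
           ktrans_mean = mean(ktrans_values),
           ktrans_sd = sd(ktrans_values),
           residual_mean = mean(resid_values),
           residual_median = median(resid_values))),
    class = "tofts_fit")
}

test_that("delta assessment is zero on self-comparison and shifts
           uniformly", {
  set.seed(20)
  r <- rexp(40); k <- runif(40, 0.05, 0.2)
  fit <- make_fit(r, k)
  same <- delta_assessment(fit, fit)
  expect_true(all(same$residuals$delta == 0))
  expect_true(all(same$ktrans$delta == 0))
  post <- make_fit(r - 0.01, k)
  shifted <- delta_assessment(fit, post)
  expect_equal(shifted$residuals$delta, rep(-0.01, 9), tolerance = 1e-12)
  # mismatched ROIs are refused
  other <- make_fit(r[1:39], k[1:39])
  expect_error(delta_assessment(fit, other), "same ROI")
})

test_that("all-decreasing pairs give the closed-form sign test p-value", {
  pre <- 1:10 + 0.5
  post <- pre - 1
  out <- paired_tests(pre, post)
  expect_equal(out$sign_test_p, 2 * 0.5^10, tolerance = 1e-12)
  expect_true(out$wilcoxon_p <= 0.01)
})

test_that("Wilcoxon signed-rank matches exhaustive enumeration for n = 8", {
  set.seed(33)
  pre <- rnorm(8)
  delta <- c(-1.3, 0.7, -2.1, 0.4, -0.9, 1.8, -0.2, -3.0)
  post <- pre + delta
  out <- paired_tests(pre, post)
  # enumerate all 2^8 sign assignments of the ranked |delta|
  r <- rank(abs(delta))
  tobs <- sum(r[delta > 0])
  tall <- vapply(0:(2^8 - 1), function(m) {
    signs <- as.integer(intToBits(m))[1:8]
    sum(r[signs == 1])
  }, 0)
  p_exact <- min(1, 2 * min(mean(tall <= tobs), mean(tall >= tobs)))
  expect_equal(out$wilcoxon_p, p_exact, tolerance = 1e-12)
})

test_that("Spearman rho is 1 for jointly monotone pre and delta", {
  pre <- c(1, 2, 3, 5, 8, 13)
  post <- pre + c(0.1, 0.2, 0.3, 0.5, 0.8, 1.3)
  out <- paired_tests(pre, post)
  expect_equal(out$spearman_rho, 1)
})

test_that("degenerate paired inputs are handled explicitly", {
  expect_error(paired_tests(1:3, 2:4), "at least 5")
  expect_message(out <- paired_tests(rep(1, 6), rep(1, 6)), "tied")
  expect_true(is.na(out$sign_test_p))
})

test_that("Kruskal-Wallis matches the hand rank-sum formula", {
  values <- c(1, 2, 3, 101, 102, 103)
  labels <- rep(c("a", "b"), each = 3)
  out <- group_comparison(values, labels)
  # H = 12/(N(N+1)) * sum(R_i^2/n_i) - 3(N+1), no ties
  H <- 12 / (6 * 7) * ((1 + 2 + 3)^2 / 3 + (4 + 5 + 6)^2 / 3) - 3 * 7
  expect_equal(out$statistic, H, tolerance = 1e-12)
  # identical groups: H = 0, p = 1 (complete ties)
  same <- group_comparison(c(1, 2, 3, 1, 2, 3), labels)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)
  # label names do not matter
  relab <- group_comparison(values, rep(c("x", "y"), each = 3))
  expect_equal(relab$p_value, out$p_value)
  expect_error(group_comparison(1:4, c("a", "a", "a", "b")),
               "at least 2 observations")
  expect_error(group_comparison(1:4, rep("a", 4)), "at least 2 groups")
})

test_that("reports have one row per case plus summary, and round-trip
           through CSV", {
  set.seed(21)
  cases <- lapply(1:6, function(i) {
    r <- rexp(30); k <- runif(30, 0.05, 0.2)
    pre <- make_fit(r, k)
    post <- make_fit(r - 0.002 * i, k * 0.98)
    delta_assessment(pre, post, nrs_pre = min(i, 10), nrs_post = 1)
  })
  rep1 <- compile_report(cases[1])
  expect_equal(nrow(rep1$cases), 1L)
  expect_equal(nrow(rep1$summary), 2L)
  report <- compile_report(cases)
  expect_equal(nrow(report$cases), 6L)
  # summary medians are medians of the per-case deltas
  expect_equal(
    report$summary$delta_ktrans_mean[report$summary$statistic == "median"],
    median(report$cases$delta_ktrans_mean))
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(report, path)
  back <- read_report(path)
  expect_equal(back$cases$delta_res_p50, report$cases$delta_res_p50)
  expect_equal(as.data.frame(back$summary),
               as.data.frame(report$summary))
  expect_equal(back$tests$wilcoxon_p_delta_res_p50,
               report$tests$wilcoxon_p_delta_res_p50)
})

test_that("summary medians reproduce simple known values", {
  r <- rexp(20); k <- runif(20, 0.05, 0.2)
  cases <- lapply(c(1, 2, 3), function(d) {
    delta_assessment(make_fit(r, k), make_fit(r - d, k))
  })
  report <- compile_report(cases)
  med <- report$summary[report$summary$statistic == "median", ]
  expect_equal(med$delta_res_p50, -2)
})
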