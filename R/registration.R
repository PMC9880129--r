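#' Registration configuration
#'
#' Settings for [register_groupwise()]. Defaults follow a coarse-to-fine
#' scheme: four resolutions (eightfold, fourfold, twofold down-sampling,
#' then the original resolution) so coarse motion is addressed before fine
#' motion, with the control-point grid refined alongside.
#'
#' @param pyramid down-sampling factors per level; positive, non-increasing,
#'   last factor 1.
#' @param iterations_per_level optimizer iterations at each level.
#' @param control_spacing control-point spacing (mm) per level; each entry
#'   must equal the previous one or halve it (dyadic refinement).
#' @param n_samples spatial samples drawn per metric/gradient evaluation.
#' @param optimizer `"gradient_descent_adaptive"` (stochastic sampling,
#'   adaptive step, default) or `"finite_difference_descent"` (deterministic
#'   full-gradient finite differences; for small test problems only).
#' @param step_size initial maximum control-point step in mm per level;
#'   `NULL` uses half the smallest voxel size of the level.
#' @param seed RNG seed for stochastic sampling.
#' @param drift_constraint keep the mean displacement across timepoints at
#'   every control point equal to zero (groupwise gauge fixing). Without a
#'   gauge the reference-free problem is underdetermined.
#' @param foreground_sampling restrict sampling to voxels whose temporal
#'   mean intensity is above background, instead of the whole field of view.
#' @param interpolation_order interpolation used during optimization (the
#'   C1 cubic convolution kernel keeps the analytic gradient consistent).
#' @param final_interpolation interpolation for the final resampling.
#' @param validation_samples size of the fixed validation sample used for
#'   step-size adaptation and the pre/post metric report.
#' @return A `registration_config` list.
#' @export
registration_config <- function(pyramid = c(8L, 4L, 2L, 1L),
                                iterations_per_level = 250L,
                                control_spacing = c(32, 16, 8, 8),
                                n_samples = 2048L,
                                optimizer = c("gradient_descent_adaptive",
                                              "finite_difference_descent"),
                                step_size = NULL,
                                seed = 0L,
                                drift_constraint = TRUE,
                                foreground_sampling = TRUE,
                                interpolation_order = 3L,
                                final_interpolation = 3L,
                                validation_samples = 4096L) {
  optimizer <- match.arg(optimizer)
  pyramid <- as.integer(pyramid)
  if (any(pyramid <= 0L) || any(diff(pyramid) > 0L) ||
      pyramid[length(pyramid)] != 1L)
    stop("pyramid factors must be positive, non-increasing, ending at 1")
  if (length(control_spacing) != length(pyramid))
    stop("control_spacing must give one spacing per pyramid level")
  if (length(control_spacing) > 1L) {
    r <- control_spacing[-1L] / control_spacing[-length(control_spacing)]
    if (any(abs(r - 1) > 1e-9 & abs(r - 0.5) > 1e-9))
      stop("control_spacing must stay equal or halve between levels")
  }
  structure(
    list(pyramid = pyramid,
         iterations_per_level = as.integer(iterations_per_level),
         control_spacing = as.numeric(control_spacing),
         n_samples = as.integer(n_samples), optimizer = optimizer,
         step_size = step_size, seed = as.integer(seed),
         drift_constraint = isTRUE(drift_constraint),
         foreground_sampling = isTRUE(foreground_sampling),
         interpolation_order = as.integer(interpolation_order),
         final_interpolation = as.integer(final_interpolation),
         validation_samples = as.integer(validation_samples)),
    class = "registration_config"
  )
}

#' Down-sample a series for a pyramid level
#'
#' Gaussian smoothing (anti-aliasing, sigma = factor / 2 voxels) followed by
#' decimation along each spatial axis; the time axis is untouched and voxel
#' spacing is multiplied by the factor. The smoothing kernel is normalized
#' after truncation with replicate borders, so constant volumes are
#' preserved exactly. Factor 1 returns the input unchanged.
#'
#' @param series a [dce_series()].
#' @param factor integer down-sampling factor, at least 1.
#' @return A [dce_series()] at the coarser resolution.
#' @export
downsample_series <- function(series, factor) {
  stopifnot(inherits(series, "dce_series"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  d <- dim(series$voxels)
  if (factor == 1L) return(series)
  if (any(factor > d[1:3]))
    stop("down-sampling factor ", factor, " exceeds a spatial dimension")
  sigma <- rep(factor / 2, 3L)
  idx <- lapply(d[1:3], function(n) seq(1L, n, by = factor))
  nd <- lengths(idx)
  out <- array(0, dim = c(nd, d[4L]))
  for (g in seq_len(d[4L])) {
    sm <- array(cpp_smooth_gaussian(as.numeric(series$voxels[, , , g]),
                                    d[1:3], sigma), dim = d[1:3])
    out[, , , g] <- sm[idx[[1]], idx[[2]], idx[[3]]]
  }
  dce_series(out, series$spacing * factor, series$times, series$affine)
}

# Voxel centers (mm) eligible for sampling: temporal-mean intensity above
# a small fraction of the dynamic range, or the whole lattice.
sampling_domain <- function(series, foreground = TRUE) {
  d <- dim(series$voxels)
  pts <- lattice_points(d[1:3], series$spacing)
  if (!foreground) return(pts)
  mv <- apply(series$voxels, 1:3, mean)
  thr <- min(mv) + 0.05 * (max(mv) - min(mv))
  sel <- as.vector(mv > thr)
  if (sum(sel) < 64L) return(pts)
  pts[sel, , drop = FALSE]
}

draw_sample_points <- function(domain_pts, n, spacing, extent) {
  i <- sample.int(nrow(domain_pts), n, replace = TRUE)
  jit <- matrix(runif(3L * n, -0.5, 0.5), n, 3L)
  p <- domain_pts[i, , drop = FALSE] + sweep(jit, 2L, spacing, `*`)
  for (a in 1:3) p[, a] <- pmin(pmax(p[, a], 0), extent[a])
  p
}

#' Groupwise four-dimensional registration of a DCE series
#'
#' Simultaneously aligns all timepoints of a dynamic series by minimizing
#' the PCA eigenvalue-compaction dissimilarity ([pca2_metric()]) over
#' per-timepoint cubic B-spline free-form deformations, in a
#' multi-resolution pyramid. No reference volume is selected; instead the
#' mean displacement over timepoints is projected to zero after every step
#' (when `drift_constraint` is on), which fixes the gauge of the otherwise
#' underdetermined reference-free problem.
#'
#' At each level the optimizer performs adaptive-step gradient descent on
#' freshly drawn spatial samples per iteration; a fixed, seeded validation
#' sample monitors progress, halves the step when the metric stalls, and
#' the best coefficients seen are retained. Non-convergence within the
#' iteration budget is not an error; a non-finite metric aborts with a
#' diagnostic.
#'
#' @param series a [dce_series()] with at least 3 timepoints.
#' @param config a [registration_config()].
#' @return An object of class `groupwise_registration`: list with `model`
#'   (the recovered [bspline_motion()], zero-temporal-mean gauge),
#'   `registered` (the resampled [dce_series()]), `metric_pre` /
#'   `metric_post` (PCA2 on the fixed validation sample, identity vs final
#'   transforms), and `config`.
#' @export
register_groupwise <- function(series, config = registration_config()) {
  stopifnot(inherits(series, "dce_series"))
  G <- n_timepoints(series)
  if (G < 3L) stop("groupwise registration needs at least 3 timepoints")
  if (config$n_samples < G) stop("n_samples must be at least the number of timepoints")
  extent <- series_extent(series)
  local_seed_eval(config$seed, {
    model <- bspline_motion(extent, config$control_spacing[1L], G)
    for (lev in seq_along(config$pyramid)) {
      if (lev > 1L &&
          config$control_spacing[lev] < config$control_spacing[lev - 1L])
        model <- subdivide_model(model, extent)
      level <- downsample_series(series, config$pyramid[lev])
      model <- optimize_level(level, model, config)
    }
    # fixed, seeded dense sample at full resolution for the reported metric
    dom <- sampling_domain(series, config$foreground_sampling)
    pts <- draw_sample_points(dom, config$validation_samples,
                              series$spacing, extent)
    pre <- sample_series(series, pts, NULL, config$interpolation_order)
    post <- sample_series(series, pts, model, config$interpolation_order)
    common <- pre$keep & post$keep
    metric_pre <- pca2_metric(
      sample_series(series, pts[common, , drop = FALSE], NULL,
                    config$interpolation_order)$values)
    metric_post <- pca2_metric(
      sample_series(series, pts[common, , drop = FALSE], model,
                    config$interpolation_order)$values)
    registered <- resample_series(series, model,
                                  order = config$final_interpolation)
    structure(
      list(model = model, registered = registered,
           metric_pre = metric_pre, metric_post = metric_post,
           config = config),
      class = "groupwise_registration"
    )
  })
}

optimize_level <- function(level, model, config) {
  extent_l <- series_extent(level)
  dom <- sampling_domain(level, config$foreground_sampling)
  s0 <- if (is.null(config$step_size)) 0.5 * min(level$spacing)
        else config$step_size
  iters <- config$iterations_per_level
  order <- config$interpolation_order
  use_fd <- identical(config$optimizer, "finite_difference_descent")
  val_pts <- draw_sample_points(dom, config$validation_samples,
                                level$spacing, extent_l)
  val_metric <- function(m)
    pca2_metric(sample_series(level, val_pts, m, order)$values)
  best <- model
  best_val <- val_metric(model)
  last_val <- best_val
  lr <- NULL
  check_every <- 25L
  for (it in seq_len(iters)) {
    pts <- draw_sample_points(dom, config$n_samples, level$spacing,
                              extent_l)
    g <- if (use_fd) {
      list(gradient = fd_metric_gradient(level, model, pts, order),
           metric = pca2_metric(sample_series(level, pts, model,
                                              order)$values))
    } else {
      pca2_gradient_core(level, model, pts, order, fd_fallback = FALSE)
    }
    if (!is.finite(g$metric))
      stop("PCA metric became non-finite during optimization")
    ginf <- max(abs(g$gradient))
    if (ginf == 0) next
    if (is.null(lr)) lr <- s0 / ginf
    decay <- 1 / (1 + 4 * (it - 1) / iters)
    step <- decay * lr * g$gradient
    sinf <- max(abs(step))
    if (sinf > s0) step <- step * (s0 / sinf)
    model$coefficients <- model$coefficients - step
    if (config$drift_constraint) model <- project_drift(model)
    if (it %% check_every == 0L || it == iters) {
      cur <- val_metric(model)
      if (cur < best_val) {
        best_val <- cur
        best <- model
      }
      if (cur >= last_val - 1e-10) lr <- lr / 2
      last_val <- cur
    }
  }
  best
}

#' @export
print.groupwise_registration <- function(x, ...) {
  cat("<groupwise_registration> ", x$model$n_times, " timepoints\n",
      sep = "")
  cat("  PCA2 metric: ", format(x$metric_pre), " (unregistered) -> ",
      format(x$metric_post), " (registered)\n", sep = "")
  invisible(x)
}

#' @rdname register_groupwise
#' @param x a `groupwise_registration` object.
#' @param ... unused.
#' @export
glance.groupwise_registration <- function(x, ...) {
  tibble::tibble(
    metric_pre = x$metric_pre,
    metric_post = x$metric_post,
    metric_change = x$metric_post - x$metric_pre,
    n_timepoints = x$model$n_times,
    levels = length(x$config$pyramid),
    max_displacement_mm = max(abs(x$model$coefficients))
  )
}
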