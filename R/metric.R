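#' Sample correlation matrix of an intensity sample matrix
#'
#' Columns (one per timepoint) are standardized to zero mean and unit
#' variance over the N spatial samples; the correlation matrix is
#' `K = t(M) %*% M / (N - 1)`. A zero-variance column (possible when all
#' samples land in signal-free background) is regularized by flooring its
#' variance at 1e-12 with a warning, rather than failing: background
#' sampling must not kill a registration run.
#'
#' @param samples N x G numeric matrix: N spatial samples of G timepoints.
#' @return G x G symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(samples) {
  samples <- as.matrix(samples)
  n <- nrow(samples)
  if (n < 2L) stop("need at least 2 spatial samples")
  std <- standardize_columns(samples)
  K <- crossprod(std) / (n - 1)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  K
}

standardize_columns <- function(samples) {
  m <- colMeans(samples)
  v <- apply(samples, 2L, var)
  if (any(v < 1e-12)) {
    warning("zero-variance column(s) in sample matrix; variance floored")
    v <- pmax(v, 1e-12)
  }
  sweep(sweep(samples, 2L, m, `-`), 2L, sqrt(v), `/`)
}

#' PCA eigenvalue-compaction dissimilarity (PCA2 metric)
#'
#' The groupwise dissimilarity `D = sum(j * lambda_j)` over the descending
#' eigenvalues of the inter-timepoint intensity correlation matrix. In a
#' well-aligned dynamic series, intensity change over time is governed by a
#' low-rank physiological process (contrast kinetics), so the leading
#' eigenvalues carry nearly all variance; motion disperses the spectrum
#' into trailing eigenvalues, which the linearly increasing weights
#' penalize. Lower D means better alignment. Since the eigenvalue trace is
#' fixed at G, D is bounded: `G <= D <= G * (G + 1) / 2`, with `D == G`
#' exactly in the rank-1 limit.
#'
#' @param samples N x G intensity sample matrix (or a precomputed G x G
#'   correlation matrix, detected by symmetry with unit diagonal).
#' @return Scalar dissimilarity.
#' @export
pca2_metric <- function(samples) {
  samples <- as.matrix(samples)
  K <- if (is_correlation(samples)) samples else sample_correlation(samples)
  lambda <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  sum(seq_along(lambda) * lambda)
}

is_correlation <- function(x) {
  nrow(x) == ncol(x) && all(abs(diag(x) - 1) < 1e-12) &&
    all(abs(x - t(x)) < 1e-12)
}

# Sample all timepoints of a series through the current transforms.
# points are world mm on the *series* lattice; rows where any timepoint's
# warped position leaves the physical domain are dropped.
# Returns list(values = N' x G, points = kept points, keep = logical,
#              grad = list of N' x 3 per-mm intensity gradients or NULL).
sample_series <- function(series, points, model = NULL, order = 3L,
                          want_gradient = FALSE) {
  d <- dim(series$voxels)
  G <- d[4L]
  ext <- series_extent(series)
  n <- nrow(points)
  vals <- matrix(0, n, G)
  grads <- if (want_gradient) vector("list", G) else NULL
  keep <- rep(TRUE, n)
  warped <- vector("list", G)
  for (g in seq_len(G)) {
    pts <- points
    if (!is.null(model)) {
      disp <- ffd_displacement(model, points, g)
      pts <- points + disp
    }
    keep <- keep &
      pts[, 1] >= 0 & pts[, 1] <= ext[1] &
      pts[, 2] >= 0 & pts[, 2] <= ext[2] &
      pts[, 3] >= 0 & pts[, 3] <= ext[3]
    warped[[g]] <- pts
  }
  for (g in seq_len(G)) {
    vox <- sweep(warped[[g]][keep, , drop = FALSE], 2L, series$spacing, `/`)
    r <- cpp_interp3(as.numeric(series$voxels[, , , g]), d[1:3], vox,
                     as.integer(order), want_gradient)
    vals_g <- r$value
    vals[seq_len(sum(keep)), g] <- vals_g
    if (want_gradient)
      grads[[g]] <- sweep(r$gradient, 2L, series$spacing, `/`)
  }
  list(values = vals[seq_len(sum(keep)), , drop = FALSE],
       points = points[keep, , drop = FALSE], keep = keep, grad = grads)
}

#' Sample an intensity matrix from a series
#'
#' Draws the N x G matrix of intensities (N spatial samples, G timepoints)
#' that the PCA metric operates on, sampling each timepoint through its
#' current transform. Rows falling outside the common image domain after
#' warping are dropped.
#'
#' @param series a [dce_series()].
#' @param points N x 3 matrix of world coordinates (mm).
#' @param model optional [bspline_motion()]; `NULL` samples the identity.
#' @param order interpolation order (1 or 3).
#' @return N' x G matrix with attribute `points` (the kept coordinates).
#' @export
sample_intensity_matrix <- function(series, points, model = NULL,
                                    order = 3L) {
  s <- sample_series(series, as.matrix(points), model, order, FALSE)
  structure(s$values, points = s$points)
}

# Analytic gradient of the PCA2 metric with respect to all per-timepoint
# B-spline coefficients, by first-order eigenvalue perturbation through the
# chain rule. Falls back to central finite differences when adjacent
# eigenvalues nearly coincide (perturbation theory breaks down).
# Returns list(metric, gradient (same shape as model$coefficients), n).
pca2_gradient_core <- function(series, model, points, order = 3L,
                               fd_fallback = TRUE, eig_tol = 1e-9) {
  G <- n_timepoints(series)
  s <- sample_series(series, points, model, order, want_gradient = TRUE)
  Y <- s$values
  n <- nrow(Y)
  if (n < max(2L, G)) stop("too few in-domain samples for the metric")
  m <- colMeans(Y)
  v <- pmax(apply(Y, 2L, var), 1e-12)
  sdev <- sqrt(v)
  M <- sweep(sweep(Y, 2L, m, `-`), 2L, sdev, `/`)
  K <- crossprod(M) / (n - 1)
  K <- (K + t(K)) / 2
  diag(K) <- 1
  ev <- eigen(K, symmetric = TRUE)
  lambda <- ev$values
  metric <- sum(seq_len(G) * lambda)
  if (!is.finite(metric)) stop("PCA metric is not finite (NaN in samples?)")
  degenerate <- any(abs(diff(lambda)) < eig_tol)
  if (fd_fallback && degenerate) {
    grad <- fd_metric_gradient(series, model, points, order)
    return(list(metric = metric, gradient = grad, n = n,
                degenerate = TRUE))
  }
  # with fd_fallback off (optimizer path) the analytic expression is used
  # even for clustered eigenvalues: any orthonormal basis of a degenerate
  # cluster yields a valid descent (sub)gradient of the weighted sum
  V <- ev$vectors
  W <- V %*% (seq_len(G) * t(V))             # V diag(1:G) V^T
  A <- M %*% W
  b <- rowSums(W * K)
  dDdY <- 2 * sweep(A - sweep(M, 2L, b, `*`), 2L, (n - 1) * sdev, `/`)
  grad <- array(0, dim = dim(model$coefficients))
  for (g in seq_len(G)) {
    vals <- dDdY[, g] * s$grad[[g]]
    sc <- cpp_ffd_scatter(s$points, vals, model$grid_dim,
                          model$control_spacing, model$origin)
    grad[, , , , g] <- array(sc, dim = c(model$grid_dim, 3L))
  }
  list(metric = metric, gradient = grad, n = n, degenerate = degenerate)
}

# Central finite differences of the metric over every coefficient.
fd_metric_gradient <- function(series, model, points, order = 3L,
                               h = 1e-3) {
  eval_metric <- function(mod) {
    Y <- sample_series(series, points, mod, order, FALSE)$values
    pca2_metric(Y)
  }
  grad <- array(0, dim = dim(model$coefficients))
  idx <- which(array(TRUE, dim = dim(model$coefficients)))
  for (i in idx) {
    mp <- model; mp$coefficients[i] <- mp$coefficients[i] + h
    mm <- model; mm$coefficients[i] <- mm$coefficients[i] - h
    grad[i] <- (eval_metric(mp) - eval_metric(mm)) / (2 * h)
  }
  grad
}

#' Gradient of the PCA2 metric with respect to motion coefficients
#'
#' Computes the analytic gradient of [pca2_metric()] with respect to every
#' per-timepoint B-spline control coefficient, by differentiating the
#' column standardization, the correlation matrix, and its eigenvalues
#' (first-order perturbation), chained through the sampled spatial
#' intensity gradients and the B-spline basis. When adjacent eigenvalues
#' differ by less than `1e-9` the analytic form is ill-conditioned and a
#' central finite-difference evaluation is used instead.
#'
#' @inheritParams sample_intensity_matrix
#' @param model a [bspline_motion()] at which to differentiate.
#' @return List with `metric` (scalar), `gradient` (array shaped like
#'   `model$coefficients`), `n` (in-domain samples used), and `degenerate`
#'   (whether the finite-difference fallback was taken).
#' @export
pca2_gradient <- function(series, model, points, order = 3L) {
  pca2_gradient_core(series, as_motion(model, series), as.matrix(points),
                     order)
}

as_motion <- function(model, series) {
  if (inherits(model, "bspline_motion")) return(model)
  stop("model must be a bspline_motion")
}
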