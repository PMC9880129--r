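#' Per-timepoint B-spline free-form deformation model
#'
#' Represents the motion of every volume of a DCE series as a cubic B-spline
#' free-form deformation: a coarse grid of control-point displacement
#' vectors (mm), interpolated to a C2-smooth dense displacement field.
#' Control point `j` (0-based) along an axis sits at `(j - 1) * delta` mm,
#' so the grid extends one spacing beyond the image domain on each side and
#' always covers the cubic support. No timepoint is a designated reference:
#' the model is groupwise, and the registration optimizer keeps the mean
#' displacement over timepoints at zero (gauge fixing); use
#' [rebase_model()] to re-express transforms relative to one timepoint.
#'
#' @param extent numeric(3): physical extent of the image domain in mm,
#'   i.e. `(dim - 1) * spacing`.
#' @param control_spacing control-point spacing in mm (scalar or length 3).
#' @param n_times number of timepoints.
#' @param coefficients optional (gx, gy, gz, 3, n_times) array of
#'   control-point displacements in mm; defaults to all zero (identity).
#' @return An object of class `bspline_motion`.
#' @export
bspline_motion <- function(extent, control_spacing, n_times,
                           coefficients = NULL) {
  extent <- as.numeric(extent)
  delta <- rep_len(as.numeric(control_spacing), 3L)
  stopifnot(length(extent) == 3L, all(extent > 0), all(delta > 0),
            n_times >= 1L)
  grid_dim <- as.integer(floor(extent / delta) + 4L)
  origin <- -delta
  if (is.null(coefficients))
    coefficients <- array(0, dim = c(grid_dim, 3L, n_times))
  stopifnot(all(dim(coefficients) == c(grid_dim, 3L, n_times)))
  structure(
    list(control_spacing = delta, grid_dim = grid_dim, origin = origin,
         extent = extent, n_times = as.integer(n_times),
         coefficients = coefficients),
    class = "bspline_motion"
  )
}

#' @export
print.bspline_motion <- function(x, ...) {
  cat("<bspline_motion> grid ", paste(x$grid_dim, collapse = " x "),
      " control points x ", x$n_times, " timepoints\n", sep = "")
  cat("  control spacing (mm): ", paste(format(x$control_spacing),
                                        collapse = " x "), "\n", sep = "")
  cat("  max |displacement| coefficient: ",
      format(max(abs(x$coefficients))), " mm\n", sep = "")
  invisible(x)
}

#' Evaluate the displacement field of one timepoint
#'
#' @param model a [bspline_motion()].
#' @param points N x 3 matrix of world coordinates in mm.
#' @param timepoint timepoint index (1-based).
#' @return N x 3 matrix of displacements in mm.
#' @export
ffd_displacement <- function(model, points, timepoint) {
  stopifnot(inherits(model, "bspline_motion"))
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, timepoint >= 1L,
            timepoint <= model$n_times)
  coef <- model$coefficients[, , , , timepoint, drop = FALSE]
  cpp_ffd_disp(points, as.numeric(coef), model$grid_dim,
               model$control_spacing, model$origin)
}

# Regular lattice of world coordinates (mm) for a series or dim/spacing.
lattice_points <- function(dim3, spacing, stride = 1L) {
  ix <- seq(0L, dim3[1] - 1L, by = stride)
  iy <- seq(0L, dim3[2] - 1L, by = stride)
  iz <- seq(0L, dim3[3] - 1L, by = stride)
  g <- as.matrix(expand.grid(x = ix, y = iy, z = iz))
  sweep(g, 2L, spacing, `*`)
}

#' Re-express a groupwise motion model relative to one timepoint
#'
#' Subtracts the reference timepoint's control coefficients from every
#' timepoint, so the reference transform becomes the identity. For smooth
#' displacements this approximates composition with the inverse reference
#' transform to first order, which is what is wanted when results must live
#' in the geometry of a chosen (typically the unenhanced) volume.
#'
#' @param model a [bspline_motion()].
#' @param reference timepoint index whose transform becomes identity.
#' @return A [bspline_motion()] with shifted coefficients.
#' @export
rebase_model <- function(model, reference = 1L) {
  stopifnot(inherits(model, "bspline_motion"))
  ref <- model$coefficients[, , , , reference]
  for (g in seq_len(model$n_times))
    model$coefficients[, , , , g] <- model$coefficients[, , , , g] - ref
  model
}

# Project coefficients onto the zero-temporal-mean gauge (groupwise
# constraint: no net drift of the common frame).
project_drift <- function(model) {
  m <- apply(model$coefficients, 1:4, mean)
  for (g in seq_len(model$n_times))
    model$coefficients[, , , , g] <- model$coefficients[, , , , g] - m
  model
}

# Dyadic refinement of cubic B-spline coefficients along every spatial axis
# (halved control spacing, identical displacement field up to boundary
# padding). Used between pyramid levels.
subdivide_model <- function(model, extent) {
  delta_new <- model$control_spacing / 2
  out <- bspline_motion(extent, delta_new, model$n_times)
  refine_1d <- function(n_old, n_new) {
    # old 0-based index i at position (i-1)*delta; new j at (j-1)*delta/2
    R <- matrix(0, n_new, n_old)
    for (j in seq_len(n_new)) {
      mp <- j - 2L                       # new position index m'
      if (mp %% 2L == 0L) {
        m <- mp %/% 2L
        for (dm in -1:1) {
          i <- m + dm + 2L               # old 1-based index
          w <- if (dm == 0L) 6 / 8 else 1 / 8
          if (i >= 1L && i <= n_old) R[j, i] <- R[j, i] + w
        }
      } else {
        m <- (mp - 1L) %/% 2L
        for (dm in 0:1) {
          i <- m + dm + 2L
          if (i >= 1L && i <= n_old) R[j, i] <- R[j, i] + 1 / 2
        }
      }
    }
    R
  }
  Rx <- refine_1d(model$grid_dim[1], out$grid_dim[1])
  Ry <- refine_1d(model$grid_dim[2], out$grid_dim[2])
  Rz <- refine_1d(model$grid_dim[3], out$grid_dim[3])
  co <- model$coefficients
  for (g in seq_len(model$n_times))
    for (a in 1:3) {
      arr <- co[, , , a, g]
      arr <- apply(arr, 2:3, function(v) Rx %*% v)        # x axis
      arr <- aperm(apply(arr, c(1, 3), function(v) Ry %*% v), c(2, 1, 3))
      arr <- aperm(apply(arr, c(1, 2), function(v) Rz %*% v), c(2, 3, 1))
      out$coefficients[, , , a, g] <- arr
    }
  out
}

# Constant-coefficient model: exact rigid translation per timepoint
# (partition of unity of the B-spline basis).
translation_model <- function(extent, control_spacing, shifts) {
  shifts <- as.matrix(shifts)
  model <- bspline_motion(extent, control_spacing, nrow(shifts))
  for (g in seq_len(nrow(shifts)))
    for (a in 1:3)
      model$coefficients[, , , a, g] <- shifts[g, a]
  model
}

#' Write a motion model to a versioned JSON transform file
#'
#' @param model a [bspline_motion()].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_motion_model <- function(model, path) {
  stopifnot(inherits(model, "bspline_motion"))
  jsonlite::write_json(
    list(format = "dcereg-bspline-motion", version = 1L,
         control_spacing_mm = model$control_spacing,
         grid_dim = model$grid_dim,
         origin_mm = model$origin,
         extent_mm = model$extent,
         n_timepoints = model$n_times,
         coefficients_mm = as.numeric(model$coefficients)),
    path, auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' Read a motion model from a JSON transform file
#'
#' @param path a file written by [write_motion_model()].
#' @return A [bspline_motion()].
#' @export
read_motion_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "dcereg-bspline-motion"))
    stop("not a dcereg motion transform file: ", path)
  coef <- array(as.numeric(j$coefficients_mm),
                dim = c(j$grid_dim, 3L, j$n_timepoints))
  bspline_motion(j$extent_mm, j$control_spacing_mm, j$n_timepoints,
                 coefficients = coef)
}

# Background fill value for resampling: median intensity of the volume's
# boundary faces.
border_value <- function(vol) {
  d <- dim(vol)
  vals <- c(vol[1, , ], vol[d[1], , ], vol[, 1, ], vol[, d[2], ],
            vol[, , 1], vol[, , d[3]])
  median(vals)
}

# Shared resampling core: volume t sampled through the timepoint-t
# deformation, out(x) = in(x + u_t(x)). Timepoints with identically zero
# coefficients are copied untouched (exact identity).
warp_series <- function(series, model, order = 3L) {
  stopifnot(inherits(series, "dce_series"), inherits(model, "bspline_motion"))
  d <- dim(series$voxels)
  if (model$n_times != d[4L])
    stop("model has ", model$n_times, " timepoints but series has ", d[4L])
  if (any(model$extent < series_extent(series) - 1e-6))
    stop("motion model does not cover the series domain")
  out <- series$voxels
  for (g in seq_len(d[4L])) {
    coef <- model$coefficients[, , , , g]
    if (all(coef == 0)) next
    vol <- series$voxels[, , , g]
    out[, , , g] <- array(
      cpp_resample_ffd(as.numeric(vol), d[1:3], series$spacing,
                       as.numeric(coef), model$grid_dim,
                       model$control_spacing, model$origin,
                       as.integer(order), border_value(vol)),
      dim = d[1:3]
    )
  }
  dce_series(out, series$spacing, series$times, series$affine)
}

#' Apply a known motion model to a series
#'
#' Corrupts (or restores) a series by resampling every volume through its
#' timepoint deformation. Used by the phantom generator to inject
#' ground-truth motion. Timepoints whose coefficients are identically zero
#' (e.g. the unenhanced reference of phantom truth motion) are returned
#' bit-identical.
#'
#' @param series a [dce_series()].
#' @param motion a [bspline_motion()] defined on the series domain.
#' @param order interpolation order: 1 (trilinear) or 3 (cubic convolution).
#' @return The resampled [dce_series()].
#' @export
apply_motion <- function(series, motion, order = 3L) {
  warp_series(series, motion, order = order)
}

#' Resample a series through a recovered motion model
#'
#' Applies the transforms found by [register_groupwise()]: each volume is
#' resampled through its timepoint transform; voxels mapped outside the
#' domain are filled with the volume's background (boundary-median) value.
#'
#' @inheritParams apply_motion
#' @param model a [bspline_motion()] covering the series domain.
#' @return The registered [dce_series()].
#' @export
resample_series <- function(series, model, order = 3L) {
  warp_series(series, model, order = order)
}
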