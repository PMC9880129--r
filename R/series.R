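#' Construct a 4D DCE-MRI series
#'
#' A `dce_series` bundles a 4D intensity array (x, y, z, t) with its voxel
#' spacing, per-volume acquisition times, and a voxel-to-world affine.
#' Times are seconds relative to contrast injection; the unenhanced volume
#' is acquired at or before 0 s.
#'
#' @param voxels 4D numeric array (x, y, z, t).
#' @param spacing numeric(3), voxel size in mm, strictly positive.
#' @param times numeric vector of acquisition times in seconds, strictly
#'   increasing, one per volume (at least 2).
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `spacing`.
#' @return An object of class `dce_series`.
#' @export
dce_series <- function(voxels, spacing, times, affine = NULL) {
  if (length(dim(voxels)) != 4L) stop("series must be 4D")
  spacing <- as.numeric(spacing)
  times <- as.numeric(times)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  if (length(times) < 2L) stop("a series needs at least 2 time points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (length(times) != dim(voxels)[4L])
    stop("number of times (", length(times), ") does not match temporal ",
         "extent of voxels (", dim(voxels)[4L], ")")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be a 4x4 matrix")
  structure(
    list(voxels = voxels, spacing = spacing, times = times, affine = affine),
    class = "dce_series"
  )
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<dce_series> ", paste(d[1:3], collapse = " x "), " voxels x ",
      d[4], " time points\n", sep = "")
  cat("  spacing (mm): ", paste(format(x$spacing), collapse = " x "), "\n",
      sep = "")
  cat("  times (s):    ", paste(format(x$times), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.dce_series <- function(x) dim(x$voxels)

n_timepoints <- function(series) dim(series$voxels)[4L]

# Physical extent of the voxel lattice (mm), per axis: (dim - 1) * spacing.
series_extent <- function(series) (dim(series$voxels)[1:3] - 1) * series$spacing

sidecar_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, ".json")
}

#' Write a DCE series to NIfTI with a JSON time sidecar
#'
#' The 4D volume goes to a NIfTI-1 file (float64, so round-trips are
#' bit-exact); acquisition times go to a `<basename>.json` sidecar as
#' `{"times_s": [...]}`, because NIfTI itself only carries a uniform
#' repetition time.
#'
#' @param series a [dce_series()].
#' @param path output path, typically ending in `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_dce_series <- function(series, path) {
  stopifnot(inherits(series, "dce_series"))
  if (any(!is.finite(series$voxels))) stop("non-finite voxel values")
  vox <- series$voxels
  attr(vox, "pixdim") <- c(series$spacing, 1)
  img <- RNifti::asNifti(vox, datatype = "double")
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(times_s = series$times, spacing_mm = series$spacing),
    sidecar_path(path), auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' Read a DCE series from NIfTI
#'
#' @param path a 4D NIfTI file written by [write_dce_series()] or any 4D
#'   NIfTI volume.
#' @param times optional acquisition times in seconds; when absent they are
#'   taken from the JSON sidecar next to `path`.
#' @return A [dce_series()].
#' @export
read_dce_series <- function(path, times = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) stop("series must be 4D")
  arr <- array(as.numeric(arr), dim = dim(arr))
  spacing <- as.numeric(RNifti::pixdim(img)[1:3])
  sc <- sidecar_path(path)
  meta <- if (file.exists(sc)) jsonlite::read_json(sc,
                                                   simplifyVector = TRUE)
          else NULL
  # header pixdim is float32; the sidecar keeps spacing at full precision
  if (!is.null(meta$spacing_mm)) spacing <- as.numeric(meta$spacing_mm)
  if (is.null(times)) {
    if (is.null(meta))
      stop("no acquisition times given and no sidecar found at ", sc)
    times <- as.numeric(meta$times_s)
  }
  if (length(times) != dim(arr)[4L])
    stop("time count mismatch: ", length(times), " times for ",
         dim(arr)[4L], " volumes")
  aff <- tryCatch(unclass(RNifti::xform(img)), error = function(e) NULL)
  dce_series(arr, spacing, times, affine = aff)
}

#' Compute subtraction images
#'
#' Subtracts the unenhanced (first) volume from every postcontrast volume.
#' Negative values are retained: the downstream residual and metric
#' computations need signed differences, and display windowing is a
#' visualization concern.
#'
#' @param series a [dce_series()] whose first time point is the unenhanced
#'   volume.
#' @return A `subtraction_series`: list with a 4D `voxels` array of
#'   `G - 1` volumes and the postcontrast `times`.
#' @export
compute_subtractions <- function(series) {
  stopifnot(inherits(series, "dce_series"))
  d <- dim(series$voxels)
  if (d[4L] < 2L) stop("need at least 2 time points to subtract")
  base <- series$voxels[, , , 1L, drop = FALSE]
  out <- array(0, dim = c(d[1:3], d[4L] - 1L))
  for (g in 2:d[4L])
    out[, , , g - 1L] <- series$voxels[, , , g] - base[, , , 1L]
  structure(
    list(voxels = out, times = series$times[-1L], spacing = series$spacing),
    class = "subtraction_series"
  )
}

#' @export
print.subtraction_series <- function(x, ...) {
  d <- dim(x$voxels)
  cat("<subtraction_series> ", paste(d[1:3], collapse = " x "),
      " voxels x ", d[4], " postcontrast volumes\n", sep = "")
  invisible(x)
}
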