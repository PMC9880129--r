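#' Choose the subtraction time point for segmentation
#'
#' Segmentation uses the time point with earliest lesion enhancement and
#' best conspicuity — normally the first postcontrast volume. Only when
#' enhancement around the seed is markedly delayed (local mean at the
#' first postcontrast time point below half its value at the second) is
#' the second postcontrast volume chosen; later time points are never
#' selected.
#'
#' @param sub a `subtraction_series` from [compute_subtractions()].
#' @param seed_point 1-based voxel coordinates of a point inside the
#'   lesion.
#' @param radius_mm radius of the local neighborhood around the seed.
#' @return 1 (first postcontrast volume) or 2 (second), as an index into
#'   the subtraction series.
#' @export
select_timepoint <- function(sub, seed_point, radius_mm = 3) {
  stopifnot(inherits(sub, "subtraction_series"))
  d <- dim(sub$voxels)
  seed_point <- as.numeric(seed_point)
  if (any(seed_point < 1) || any(seed_point > d[1:3]))
    stop("seed point outside the image domain")
  ball <- ellipsoid_mask(d[1:3], sub$spacing, seed_point,
                         rep(radius_mm, 3L))
  m1 <- mean(sub$voxels[, , , 1L][ball])
  if (d[4L] < 2L) return(1L)
  m2 <- mean(sub$voxels[, , , 2L][ball])
  if (m1 <= 0 && m2 <= 0) {
    warning("no enhancement around seed; defaulting to first postcontrast")
    return(1L)
  }
  if (m1 < 0.5 * m2) 2L else 1L
}

#' Semiautomatic lesion segmentation by fractional thresholding
#'
#' Mimics a spheroid brush tool on a subtraction volume: within an
#' anisotropy-aware spheroid of radius `brush_mm` around the seed, the
#' maximum intensity M is taken and voxels with intensity strictly above
#' `fraction * M` are selected, then restricted to the 26-connected
#' component containing (or nearest to) the seed so bright structures at
#' the brush edge do not join the ROI.
#'
#' @param volume 3D subtraction volume.
#' @param seed_point 1-based voxel coordinates inside the lesion.
#' @param brush_mm brush radius in mm.
#' @param spacing voxel spacing in mm.
#' @param fraction intensity threshold as a fraction of the brush maximum.
#' @param source_timepoint optional index of the subtraction volume used
#'   (bookkeeping only).
#' @return A `lesion_roi`: list with logical `mask`, `threshold_fraction`,
#'   and `source_timepoint`.
#' @export
threshold_segment <- function(volume, seed_point, brush_mm,
                              spacing = c(1, 1, 1), fraction = 0.1,
                              source_timepoint = NA_integer_) {
  stopifnot(is.array(volume), length(dim(volume)) == 3L)
  d <- dim(volume)
  seed_point <- as.numeric(seed_point)
  if (any(seed_point < 1) || any(seed_point > d))
    stop("seed point outside the image domain")
  brush <- ellipsoid_mask(d, spacing, seed_point, rep(brush_mm, 3L))
  if (!any(brush)) stop("brush does not intersect the image domain")
  M <- max(volume[brush])
  if (M <= 0) stop("no enhancing lesion under brush")
  mask <- brush & (volume > fraction * M)
  seed_i <- round(seed_point)
  if (!mask[seed_i[1], seed_i[2], seed_i[3]]) {
    cand <- which(mask, arr.ind = TRUE)
    dd <- sweep(cand, 2L, seed_i, `-`)
    dd <- sweep(dd, 2L, spacing, `*`)
    seed_i <- cand[which.min(rowSums(dd^2)), ]
  }
  comp <- cpp_label_component(as.integer(mask), d,
                              as.integer(seed_i - 1L))
  mask <- array(comp == 1L, dim = d)
  structure(
    list(mask = mask, threshold_fraction = fraction,
         source_timepoint = source_timepoint),
    class = "lesion_roi"
  )
}

#' @export
print.lesion_roi <- function(x, ...) {
  cat("<lesion_roi> ", sum(x$mask), " voxels (threshold fraction ",
      x$threshold_fraction, ")\n", sep = "")
  invisible(x)
}

# Discrete ball structuring element: voxel offsets with Euclidean norm
# <= radius (radius 1 gives the 7-voxel 6-connectivity ball).
ball_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  as.matrix(g[g$x^2 + g$y^2 + g$z^2 <= radius^2, , drop = FALSE])
}

#' Morphological adjustment of a lesion ROI
#'
#' 3D binary dilation or erosion with a ball structuring element, the
#' manual post-editing step of semiautomatic segmentation.
#'
#' @param roi a `lesion_roi` (or logical 3D mask).
#' @param operation `"dilate"` or `"erode"`.
#' @param radius_vox structuring-element radius in voxels, `>= 1`.
#' @return The adjusted `lesion_roi`.
#' @export
morph_adjust <- function(roi, operation = c("dilate", "erode"),
                         radius_vox = 1L) {
  operation <- match.arg(operation)
  if (radius_vox < 1L) stop("radius_vox must be >= 1")
  is_roi <- inherits(roi, "lesion_roi")
  mask <- roi_mask(roi)
  d <- dim(mask)
  out <- cpp_binary_morph(as.integer(mask), d, ball_offsets(radius_vox),
                          operation == "dilate")
  out <- array(out == 1L, dim = d)
  if (operation == "erode" && !any(out)) stop("ROI vanished")
  if (is_roi) {
    roi$mask <- out
    roi
  } else {
    structure(list(mask = out, threshold_fraction = NA_real_,
                   source_timepoint = NA_integer_),
              class = "lesion_roi")
  }
}
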