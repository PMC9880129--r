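#' Phantom configuration
#'
#' Describes a synthetic breast-DCE acquisition: a desk-scale grid (64 x 64
#' x 16 by default, so full-pipeline runs stay fast) at the clinical voxel
#' spacing of 0.7 x 0.7 mm in-plane with 2 mm slices, six time points
#' (unenhanced, +90 s, then every 70 s), two ellipsoidal breast-like
#' background regions with smooth baseline texture and mild parenchymal
#' enhancement, one spherical lesion with extended-Tofts kinetics, smooth
#' inter-timepoint patient motion, and additive noise.
#'
#' @param shape spatial grid dimensions (3 integers).
#' @param spacing voxel spacing in mm.
#' @param times acquisition times in seconds.
#' @param lesion list: `center` (1-based voxel coords), `radius_mm`, and
#'   Tofts parameters `ktrans` (1/min), `ve`, `vp`.
#' @param background list of regions, each with `center` (voxel coords),
#'   `semi_axes_mm`, `baseline` intensity, and optional mild Tofts
#'   parameters `ktrans`, `ve`, `vp`.
#' @param motion_mode `"none"`, `"rigid"` (per-timepoint translation) or
#'   `"bspline"` (smooth free-form deformation).
#' @param motion_amplitude maximum control-point displacement in mm per
#'   timepoint.
#' @param motion_control_spacing control-grid spacing (mm) of the injected
#'   motion; coarser than the registration default so ground-truth motion
#'   is not trivially representable by the recovering transform.
#' @param noise_sigma additive noise SD relative to the baseline signal
#'   (e.g. 0.02 for 2 percent).
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param signal_mode `"linear"` (signal change proportional to tissue
#'   concentration; subtraction-friendly) or `"spgr"` (spoiled gradient
#'   echo signal equation: flip 25 degrees, TR 7.5 ms, relaxivity
#'   4.5 /s/mM, baseline T1 1 s).
#' @param baseline baseline tissue intensity (arbitrary units).
#' @param air_value background (air) intensity.
#' @param texture_amplitude relative SD of the smooth baseline texture.
#' @param enhancement_gain signal units per mM in linear mode.
#' @param aif the arterial input function driving enhancement.
#' @param seed integer RNG seed; identical configs reproduce bit-for-bit.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(64L, 64L, 16L),
                           spacing = c(0.7, 0.7, 2.0),
                           times = c(0, 90, 160, 230, 300, 370),
                           lesion = list(center = c(16, 36, 8),
                                         radius_mm = 5.6,
                                         ktrans = 0.103, ve = 0.3,
                                         vp = 0.02),
                           background = NULL,
                           motion_mode = c("none", "rigid", "bspline"),
                           motion_amplitude = 0,
                           motion_control_spacing = 24,
                           noise_sigma = 0,
                           noise_model = c("gaussian", "rician"),
                           signal_mode = c("linear", "spgr"),
                           baseline = 100,
                           air_value = 2,
                           texture_amplitude = 0.1,
                           enhancement_gain = 1,
                           aif = aif_weinmann(),
                           seed = 0L) {
  motion_mode <- match.arg(motion_mode)
  noise_model <- match.arg(noise_model)
  signal_mode <- match.arg(signal_mode)
  shape <- as.integer(shape)
  if (is.null(background)) {
    cx <- shape[1] / 4
    background <- list(
      list(center = c(cx, shape[2] / 2, shape[3] / 2),
           semi_axes_mm = c(10, 16, 11), baseline = baseline,
           ktrans = 0.008, ve = 0.15, vp = 0.003),
      list(center = c(3 * cx, shape[2] / 2, shape[3] / 2),
           semi_axes_mm = c(10, 16, 11), baseline = baseline,
           ktrans = 0.008, ve = 0.15, vp = 0.003)
    )
  }
  tofts_params(lesion$ktrans, lesion$ve, lesion$vp)   # validates
  if (motion_amplitude < 0) stop("motion_amplitude must be >= 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  ext <- (shape - 1L) * spacing
  cmm <- (lesion$center - 1) * spacing
  if (any(cmm - lesion$radius_mm < 0) || any(cmm + lesion$radius_mm > ext))
    stop("lesion extends outside grid")
  structure(
    list(shape = shape, spacing = as.numeric(spacing),
         times = as.numeric(times), lesion = lesion,
         background = background, motion_mode = motion_mode,
         motion_amplitude = motion_amplitude,
         motion_control_spacing = motion_control_spacing,
         noise_sigma = noise_sigma, noise_model = noise_model,
         signal_mode = signal_mode, baseline = baseline,
         air_value = air_value, texture_amplitude = texture_amplitude,
         enhancement_gain = enhancement_gain, aif = aif,
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# Ellipsoid mask in voxel space, anisotropy-aware (semi-axes in mm).
ellipsoid_mask <- function(shape, spacing, center_vox, semi_axes_mm) {
  ax <- ((seq_len(shape[1]) - center_vox[1]) * spacing[1] /
           semi_axes_mm[1])^2
  ay <- ((seq_len(shape[2]) - center_vox[2]) * spacing[2] /
           semi_axes_mm[2])^2
  az <- ((seq_len(shape[3]) - center_vox[3]) * spacing[3] /
           semi_axes_mm[3])^2
  outer(outer(ax, ay, `+`), az, `+`) <= 1
}

spgr_signal <- function(conc, t10 = 1.0, tr_s = 0.0075, flip_deg = 25,
                        relaxivity = 4.5) {
  r1 <- 1 / t10 + relaxivity * conc
  e1 <- exp(-tr_s * r1)
  a <- flip_deg * pi / 180
  sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

#' Generate a synthetic DCE phantom with known truth
#'
#' Renders a clean (motion- and noise-free) series from the configured
#' anatomy and Tofts kinetics, then corrupts it with the configured motion
#' and noise. Identical configurations (including the seed) reproduce the
#' output bit-for-bit; with `motion_mode = "none"` and `noise_sigma = 0`
#' the returned series equals the clean series exactly.
#'
#' @param config a [phantom_config()].
#' @return List with `series` (the corrupted [dce_series()]) and `truth`:
#'   `lesion_mask`, `ktrans_map` / `ve_map` / `vp_map`, `motion` (the
#'   injected [bspline_motion()], identity at the unenhanced timepoint),
#'   and `clean_series`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  local_seed_eval(config$seed, {
    shape <- config$shape
    sp <- config$spacing
    G <- length(config$times)
    ext <- (shape - 1L) * sp

    lesion_mask <- ellipsoid_mask(shape, sp, config$lesion$center,
                                  rep(config$lesion$radius_mm, 3L))
    region_masks <- lapply(config$background, function(r)
      ellipsoid_mask(shape, sp, r$center, r$semi_axes_mm))

    baselines <- array(config$air_value, dim = shape)
    ktrans_map <- array(0, dim = shape)
    ve_map <- array(0, dim = shape)
    vp_map <- array(0, dim = shape)
    for (i in seq_along(region_masks)) {
      m <- region_masks[[i]]
      r <- config$background[[i]]
      baselines[m] <- r$baseline
      if (!is.null(r$ktrans)) {
        ktrans_map[m] <- r$ktrans
        ve_map[m] <- r$ve
        vp_map[m] <- r$vp
      }
    }
    ktrans_map[lesion_mask] <- config$lesion$ktrans
    ve_map[lesion_mask] <- config$lesion$ve
    vp_map[lesion_mask] <- config$lesion$vp

    if (config$texture_amplitude > 0) {
      tex <- array(rnorm(prod(shape)), dim = shape)
      tex <- array(cpp_smooth_gaussian(as.numeric(tex), shape,
                                       rep(2, 3L)), dim = shape)
      tex <- tex / sd(tex)
      inside <- Reduce(`|`, region_masks)
      baselines[inside] <- baselines[inside] *
        (1 + config$texture_amplitude * tex[inside])
    }

    # per-tissue concentration curves (uniform parameters within tissue)
    conc <- array(0, dim = c(shape, G))
    tissues <- unique(data.frame(k = as.vector(ktrans_map),
                                 ve = as.vector(ve_map),
                                 vp = as.vector(vp_map)))
    for (r in seq_len(nrow(tissues))) {
      tt <- tissues[r, ]
      if (tt$k == 0 && tt$vp == 0) next
      sel <- ktrans_map == tt$k & ve_map == tt$ve & vp_map == tt$vp
      curve <- tofts_concentration(
        config$times, tofts_params(tt$k, max(tt$ve, 1e-6), tt$vp),
        config$aif)
      for (g in seq_len(G)) {
        vol <- conc[, , , g]
        vol[sel] <- curve[g]
        conc[, , , g] <- vol
      }
    }

    clean <- array(0, dim = c(shape, G))
    for (g in seq_len(G)) {
      cg <- conc[, , , g]
      clean[, , , g] <- if (config$signal_mode == "linear") {
        baselines * (1 + config$enhancement_gain * cg)
      } else {
        baselines * spgr_signal(cg) / spgr_signal(0)
      }
    }
    clean_series <- dce_series(clean, sp, config$times)

    motion <- phantom_motion(config, ext, G)
    series <- if (config$motion_mode == "none") clean_series
              else apply_motion(clean_series, motion)
    if (config$noise_sigma > 0)
      series <- add_noise(series,
                          config$noise_sigma * config$baseline,
                          seed = config$seed + 1L,
                          model = config$noise_model)
    list(series = series,
         truth = list(lesion_mask = lesion_mask, ktrans_map = ktrans_map,
                      ve_map = ve_map, vp_map = vp_map, motion = motion,
                      clean_series = clean_series))
  })
}

# Injected ground-truth motion: identity at the unenhanced timepoint,
# smooth random-walk drift across timepoints, scaled so the largest
# control-point displacement equals motion_amplitude.
phantom_motion <- function(config, ext, G) {
  model <- bspline_motion(ext, config$motion_control_spacing, G)
  if (config$motion_mode == "none" || config$motion_amplitude == 0)
    return(model)
  if (config$motion_mode == "rigid") {
    steps <- matrix(rnorm(3L * (G - 1L)), G - 1L, 3L)
    shifts <- rbind(0, apply(steps, 2L, cumsum))
    shifts <- shifts * (config$motion_amplitude / max(abs(shifts)))
    return(translation_model(ext, config$motion_control_spacing, shifts))
  }
  ncp <- prod(model$grid_dim) * 3L
  walk <- array(0, dim = c(model$grid_dim, 3L, G))
  acc <- array(0, dim = c(model$grid_dim, 3L))
  for (g in 2:G) {
    acc <- acc + array(rnorm(ncp), dim = c(model$grid_dim, 3L))
    walk[, , , , g] <- acc
  }
  walk <- walk * (config$motion_amplitude / max(abs(walk)))
  model$coefficients <- walk
  model
}

#' Add voxel-wise noise to a series
#'
#' Independent zero-mean Gaussian noise (or Rician magnitude noise) of
#' standard deviation `sigma` in intensity units, seeded and reproducible.
#'
#' @param series a [dce_series()].
#' @param sigma noise SD in intensity units, `>= 0`.
#' @param seed integer RNG seed.
#' @param model `"gaussian"` or `"rician"`.
#' @return The noisy [dce_series()]; `sigma = 0` returns the input
#'   unchanged.
#' @export
add_noise <- function(series, sigma, seed = 0L,
                      model = c("gaussian", "rician")) {
  stopifnot(inherits(series, "dce_series"))
  model <- match.arg(model)
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(series)
  local_seed_eval(seed, {
    n <- length(series$voxels)
    series$voxels <- if (model == "gaussian") {
      series$voxels + array(rnorm(n, sd = sigma), dim = dim(series$voxels))
    } else {
      re <- series$voxels + array(rnorm(n, sd = sigma),
                                  dim = dim(series$voxels))
      im <- array(rnorm(n, sd = sigma), dim = dim(series$voxels))
      sqrt(re^2 + im^2)
    }
    series
  })
}
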