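#' Biexponential population arterial input function
#'
#' Plasma contrast concentration `Cp(t) = D * (a1 * exp(-m1 * t') + a2 *
#' exp(-m2 * t'))` with `t'` in minutes. Defaults are the classic
#' Weinmann-type population constants for a standard 0.1 mmol/kg
#' gadolinium dose.
#'
#' @param dose contrast dose D in mmol/kg.
#' @param a1,a2 amplitudes in kg/L.
#' @param m1,m2 decay rates in 1/min.
#' @return An object of class `aif`.
#' @export
aif_weinmann <- function(dose = 0.1, a1 = 3.99, a2 = 4.78,
                         m1 = 0.144, m2 = 0.0111) {
  structure(list(form = "biexponential", dose = dose, a1 = a1, a2 = a2,
                 m1 = m1, m2 = m2), class = "aif")
}

#' Arterial input function from sampled values
#'
#' Linear interpolation between samples; zero before the first sample and
#' constant extrapolation of the last value afterwards.
#'
#' @param times_s sample times in seconds (increasing).
#' @param conc_mM plasma concentrations in mM.
#' @return An object of class `aif`.
#' @export
aif_sampled <- function(times_s, conc_mM) {
  stopifnot(length(times_s) == length(conc_mM), !is.unsorted(times_s),
            all(conc_mM >= 0))
  structure(list(form = "user_sampled", times_s = as.numeric(times_s),
                 conc_mM = as.numeric(conc_mM)), class = "aif")
}

#' Evaluate an arterial input function
#'
#' @param aif an [aif_weinmann()] or [aif_sampled()] object.
#' @param t time(s) in seconds, non-negative.
#' @return Plasma concentration(s) in mM.
#' @export
aif_value <- function(aif, t) {
  stopifnot(inherits(aif, "aif"))
  if (any(t < 0)) stop("negative time passed to aif_value")
  if (aif$form == "biexponential") {
    tm <- t / 60
    aif$dose * (aif$a1 * exp(-aif$m1 * tm) + aif$a2 * exp(-aif$m2 * tm))
  } else {
    out <- stats::approx(aif$times_s, aif$conc_mM, xout = t,
                         rule = 2, yleft = 0)$y
    out[t < aif$times_s[1L]] <- 0
    out
  }
}

#' Extended Tofts parameter set
#'
#' @param ktrans volume transfer constant in 1/min, `>= 0`.
#' @param ve extravascular-extracellular volume fraction, in (0, 1].
#' @param vp plasma volume fraction, in [0, 1); `ve + vp <= 1`.
#' @return A `tofts_params` list.
#' @export
tofts_params <- function(ktrans, ve, vp) {
  if (ktrans < 0) stop("ktrans must be >= 0")
  if (ve <= 0 && ktrans > 0)
    stop("ve = 0 with ktrans > 0 leaves k_ep undefined")
  if (ve < 0 || ve > 1) stop("ve must lie in (0, 1]")
  if (vp < 0 || vp >= 1) stop("vp must lie in [0, 1)")
  if (ve + vp > 1) stop("ve + vp must not exceed 1")
  structure(list(ktrans = ktrans, ve = ve, vp = vp),
            class = "tofts_params")
}

#' Extended Tofts tissue concentration
#'
#' `C_t(t) = vp * Cp(t) + ktrans * integral_0^t Cp(tau) *
#' exp(-(ktrans / ve) * (t - tau)) dtau`, with rates in 1/min. For a
#' biexponential AIF the convolution has a closed form; for a sampled AIF
#' a fine-grid trapezoid convolution is used.
#'
#' @param times time points in seconds, non-negative and increasing.
#' @param params a [tofts_params()].
#' @param aif an [aif_weinmann()] or [aif_sampled()] object.
#' @param dt_s integration step (s) for the numerical convolution path.
#' @return Tissue concentration in mM at `times`.
#' @export
tofts_concentration <- function(times, params, aif = aif_weinmann(),
                                dt_s = 0.1) {
  stopifnot(inherits(params, "tofts_params"))
  if (any(times < 0) || is.unsorted(times, strictly = FALSE))
    stop("times must be non-negative and increasing")
  vp_term <- params$vp * aif_value(aif, times)
  if (params$ktrans == 0) return(vp_term)
  kep <- params$ktrans / params$ve
  tm <- times / 60
  if (aif$form == "biexponential") {
    conv_term <- function(a, m) {
      if (abs(kep - m) < 1e-10) return(a * tm * exp(-m * tm))
      a * (exp(-m * tm) - exp(-kep * tm)) / (kep - m)
    }
    vp_term + params$ktrans * aif$dose *
      (conv_term(aif$a1, aif$m1) + conv_term(aif$a2, aif$m2))
  } else {
    sapply(seq_along(times), function(i) {
      t_i <- times[i]
      if (t_i == 0) return(vp_term[i])
      grid <- seq(0, t_i, by = dt_s)
      if (grid[length(grid)] < t_i) grid <- c(grid, t_i)
      f <- aif_value(aif, grid) * exp(-kep * (t_i - grid) / 60)
      integ <- sum(diff(grid) * (head(f, -1) + f[-1]) / 2) / 60 # min units
      vp_term[i] + params$ktrans * integ
    })
  }
}

#' Model-predicted relative enhancement
#'
#' The quantity fitted to the data: relative signal enhancement with
#' respect to the first (unenhanced) acquisition, `(S(t) - S(t1)) / S(t1)`.
#' Assuming signal change proportional to tissue concentration (no T1
#' mapping in the acquisition protocol), this equals
#' `(C_t(t) - C_t(t1)) / (1 + C_t(t1))`; the unknown proportionality
#' constant is absorbed into the fitted `ktrans` and `vp` (AIF-normalized
#' units), leaving `ve = ktrans / kep` unaffected.
#'
#' @inheritParams tofts_concentration
#' @return Relative enhancement at `times`, zero at the first time point.
#' @export
tofts_rel_enhancement <- function(times, params, aif = aif_weinmann()) {
  ct <- tofts_concentration(times, params, aif)
  (ct - ct[1L]) / (1 + ct[1L])
}

default_tofts_bounds <- function() {
  list(lower = c(ktrans = 0, ve = 0.01, vp = 0),
       upper = c(ktrans = 5, ve = 1, vp = 0.5))
}

# Deterministic multistart grid (no RNG in fitting).
tofts_start_grid <- function() {
  # the null start lets flat (non-enhancing) curves settle at zero
  # transfer instead of wandering along the ktrans/ve ridge
  rbind(c(ktrans = 0, ve = 0.3, vp = 0),
        as.matrix(expand.grid(ktrans = c(0.05, 0.3, 1),
                              ve = c(0.05, 0.15, 0.3, 0.6),
                              vp = c(0.005, 0.05))))
}

# Fast closed-form relative-enhancement model for a biexponential AIF with
# per-curve precomputation shared across optimizer iterations.
make_enhancement_model <- function(times, aif) {
  if (aif$form == "biexponential") {
    tm <- times / 60
    e1 <- exp(-aif$m1 * tm)
    e2 <- exp(-aif$m2 * tm)
    cp <- aif$dose * (aif$a1 * e1 + aif$a2 * e2)
    function(theta) {
      ktrans <- theta[1L]; ve <- theta[2L]; vp <- theta[3L]
      ct <- vp * cp
      if (ktrans > 0) {
        kep <- ktrans / ve
        ek <- exp(-kep * tm)
        c1 <- if (abs(kep - aif$m1) < 1e-10) aif$a1 * tm * e1
              else aif$a1 * (e1 - ek) / (kep - aif$m1)
        c2 <- if (abs(kep - aif$m2) < 1e-10) aif$a2 * tm * e2
              else aif$a2 * (e2 - ek) / (kep - aif$m2)
        ct <- ct + ktrans * aif$dose * (c1 + c2)
      }
      (ct - ct[1L]) / (1 + ct[1L])
    }
  } else {
    function(theta) {
      p <- tofts_params(theta[1L], theta[2L], theta[3L])
      tofts_rel_enhancement(times, p, aif)
    }
  }
}

#' Fit the extended Tofts model to one voxel curve
#'
#' Bounded nonlinear least squares of the relative-enhancement model
#' ([tofts_rel_enhancement()]) over `(ktrans, ve, vp)`. A deterministic
#' multistart grid guards against local minima: the sum of squares is
#' evaluated at every grid start and the best `refine` starts are polished
#' with L-BFGS-B. The residual is the root-mean-square misfit over the
#' time points used.
#'
#' @param curve relative-enhancement values, one per time point.
#' @param times acquisition times in seconds (same length, at least 4).
#' @param aif the arterial input function.
#' @param lower,upper named bounds on `(ktrans, ve, vp)`.
#' @param starts multistart grid (rows of `ktrans, ve, vp`).
#' @param refine how many of the best starts to polish.
#' @return List with `params` ([tofts_params()]), `residual` (RMSE),
#'   `n_timepoints`, and `sse`.
#' @export
fit_tofts_voxel <- function(curve, times, aif = aif_weinmann(),
                            lower = default_tofts_bounds()$lower,
                            upper = default_tofts_bounds()$upper,
                            starts = tofts_start_grid(), refine = 4L) {
  ok <- is.finite(curve)
  if (!any(ok)) stop("all-NaN voxel curve")
  if (length(curve) != length(times)) stop("curve/times length mismatch")
  if (sum(ok) < 4L) stop("need at least 4 usable time points")
  y <- curve[ok]
  model <- make_enhancement_model(times[ok], aif)
  sse <- function(theta) {
    r <- model(theta) - y
    sum(r * r)
  }
  start_sse <- apply(starts, 1L, sse)
  pick <- order(start_sse)[seq_len(min(refine, nrow(starts)))]
  best <- NULL
  for (i in pick) {
    fit <- optim(starts[i, ], sse, method = "L-BFGS-B", lower = lower,
                 upper = upper,
                 control = list(maxit = 500L, factr = 10,
                                pgtol = 1e-12,
                                parscale = c(0.1, 0.1, 0.01),
                                ndeps = rep(1e-7, 3L)))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # restart once from the incumbent: L-BFGS-B resets its memory, which
  # reliably gains a few digits on noiseless curves
  polish <- optim(best$par, sse, method = "L-BFGS-B", lower = lower,
                  upper = upper,
                  control = list(maxit = 500L, factr = 10, pgtol = 1e-14,
                                 parscale = c(0.1, 0.1, 0.01),
                                ndeps = rep(1e-7, 3L)))
  if (polish$value < best$value) best <- polish
  theta <- best$par
  # box-constrained only: very noisy voxels may end on a corner where
  # ve + vp exceeds 1, which the strict constructor would reject
  params <- structure(list(ktrans = unname(theta[1L]),
                           ve = unname(theta[2L]),
                           vp = unname(theta[3L])),
                      class = "tofts_params")
  list(params = params,
       residual = sqrt(best$value / length(y)),
       n_timepoints = length(y), sse = best$value)
}

#' Voxel-wise extended Tofts fitting over a lesion ROI
#'
#' Converts each ROI voxel's signal curve to relative enhancement with
#' respect to the unenhanced volume and fits the extended Tofts model,
#' producing `ktrans`, `ve`, `vp`, and residual (RMSE) maps that are `NaN`
#' outside the ROI, plus summary statistics over the ROI.
#'
#' @param series a [dce_series()] with at least 4 time points.
#' @param roi a `lesion_roi` or a logical 3D mask on the series grid.
#' @param aif the arterial input function.
#' @param ... passed to [fit_tofts_voxel()].
#' @return An object of class `tofts_fit` with fields `ktrans`, `ve`,
#'   `vp`, `residual` (3D maps), `roi` (logical mask), `n_timepoints`,
#'   and `summary` (tibble).
#' @export
fit_tofts_roi <- function(series, roi, aif = aif_weinmann(), ...) {
  stopifnot(inherits(series, "dce_series"))
  mask <- roi_mask(roi)
  d <- dim(series$voxels)
  if (!all(dim(mask) == d[1:3])) stop("roi and series grids do not match")
  if (!any(mask)) stop("empty ROI")
  if (d[4L] < 4L) stop("need at least 4 time points for Tofts fitting")
  idx <- which(mask)
  nvol <- prod(d[1:3])
  base <- as.numeric(series$voxels[, , , 1L])[idx]
  base <- pmax(base, 1e-6)
  maps <- list(ktrans = rep(NaN, nvol), ve = rep(NaN, nvol),
               vp = rep(NaN, nvol), residual = rep(NaN, nvol))
  vox <- matrix(series$voxels, nrow = nvol)[idx, , drop = FALSE]
  enh <- sweep(sweep(vox, 1L, base, `-`), 1L, base, `/`)
  for (k in seq_along(idx)) {
    f <- fit_tofts_voxel(enh[k, ], series$times, aif, ...)
    maps$ktrans[idx[k]] <- f$params$ktrans
    maps$ve[idx[k]] <- f$params$ve
    maps$vp[idx[k]] <- f$params$vp
    maps$residual[idx[k]] <- f$residual
  }
  maps <- lapply(maps, array, dim = d[1:3])
  kt <- maps$ktrans[mask]
  structure(
    list(ktrans = maps$ktrans, ve = maps$ve, vp = maps$vp,
         residual = maps$residual, roi = mask, n_timepoints = d[4L],
         summary = tibble::tibble(
           n_voxels = length(idx),
           ktrans_mean = mean(kt), ktrans_sd = sd(kt),
           residual_mean = mean(maps$residual[mask]),
           residual_median = median(maps$residual[mask]))),
    class = "tofts_fit"
  )
}

roi_mask <- function(roi) {
  if (inherits(roi, "lesion_roi")) return(roi$mask)
  if (is.array(roi) && length(dim(roi)) == 3L) return(roi != 0)
  stop("roi must be a lesion_roi or a 3D mask array")
}

#' @export
print.tofts_fit <- function(x, ...) {
  s <- x$summary
  cat("<tofts_fit> ", s$n_voxels, " ROI voxels, ", x$n_timepoints,
      " time points\n", sep = "")
  cat("  ktrans: mean ", format(s$ktrans_mean, digits = 4), " /min, SD ",
      format(s$ktrans_sd, digits = 4), "\n", sep = "")
  cat("  residual (RMSE): mean ", format(s$residual_mean, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' @rdname fit_tofts_roi
#' @param x a `tofts_fit` object.
#' @export
tidy.tofts_fit <- function(x, ...) {
  idx <- which(x$roi, arr.ind = TRUE)
  mask <- x$roi
  out <- tibble::tibble(
    x = idx[, 1L], y = idx[, 2L], z = idx[, 3L]
  )
  out$ktrans <- x$ktrans[mask]
  out$ve <- x$ve[mask]
  out$vp <- x$vp[mask]
  out$residual <- x$residual[mask]
  out
}

#' @rdname fit_tofts_roi
#' @export
glance.tofts_fit <- function(x, ...) x$summary

#' Percentiles of the intralesion residual-error distribution
#'
#' Empirical percentiles (linear-interpolation convention) of the
#' voxel-wise perfusion-model residual over the ROI, enabling
#' percentile-wise assessment of where modeling uncertainty concentrates.
#'
#' @param fit a `tofts_fit`, or a 3D residual map (then `roi` is required).
#' @param roi optional ROI when `fit` is a bare map.
#' @param percentiles percentile levels in (0, 100).
#' @return A tibble with columns `percentile` and `value`.
#' @export
residual_percentiles <- function(fit, roi = NULL,
                                 percentiles = seq(10, 90, by = 10)) {
  if (inherits(fit, "tofts_fit")) {
    vals <- fit$residual[fit$roi]
  } else {
    if (is.null(roi)) stop("roi required when passing a bare residual map")
    mask <- roi_mask(roi)
    if (!any(mask)) stop("empty ROI")
    vals <- fit[mask]
  }
  tibble::tibble(
    percentile = as.numeric(percentiles),
    value = as.numeric(quantile(vals, percentiles / 100, type = 7,
                                names = FALSE))
  )
}
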