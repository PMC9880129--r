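# Small in-memory fixtures built in code.

# A tiny random series (not smooth; for I/O and bookkeeping tests).
tiny_series <- function(dims = c(8, 8, 4), G = 3, seed = 1,
                        spacing = c(0.7, 0.7, 2),
                        times = seq(0, by = 70, length.out = G) +
                          c(0, rep(20, G - 1))) {
  set.seed(seed)
  dce_series(array(rnorm(prod(dims) * G), c(dims, G)), spacing, times)
}

# A small smooth multi-timepoint series: shared smooth anatomy plus smooth
# per-timepoint variation, suitable for metric-gradient checks.
smooth_series <- function(dims = c(8, 8, 4), G = 3, seed = 1,
                          spacing = c(1, 1, 2), noise = 0.2) {
  set.seed(seed)
  smooth3 <- function() {
    a <- array(rnorm(prod(dims)), dims)
    array(dcereg:::cpp_smooth_gaussian(as.numeric(a), dims,
                                       c(1.5, 1.5, 1)), dims)
  }
  base <- smooth3()
  vox <- array(0, c(dims, G))
  for (g in seq_len(G))
    vox[, , , g] <- base * (1 + 0.1 * g) + noise * smooth3()
  dce_series(vox, spacing, seq(0, by = 70, length.out = G))
}

# Desk-scale phantom configuration shrunk further for unit tests.
small_phantom_config <- function(...,
                                 lesion = list(center = c(8, 18, 5),
                                               radius_mm = 3.5,
                                               ktrans = 0.103, ve = 0.3,
                                               vp = 0.02),
                                 background = list(
                                   list(center = c(8, 16, 5.5),
                                        semi_axes_mm = c(5, 9, 7),
                                        baseline = 100, ktrans = 0.008,
                                        ve = 0.15, vp = 0.003),
                                   list(center = c(24, 16, 5.5),
                                        semi_axes_mm = c(5, 9, 7),
                                        baseline = 100, ktrans = 0.008,
                                        ve = 0.15, vp = 0.003))) {
  phantom_config(shape = c(32L, 32L, 10L), spacing = c(0.7, 0.7, 2.0),
                 lesion = lesion, background = background, ...)
}

# Displacement comparison points inside breast tissue (world mm).
breast_points <- function(phantom, thin = 17L, thr = 10) {
  mv <- apply(phantom$truth$clean_series$voxels, 1:3, mean)
  d3 <- dim(mv)
  pts <- dcereg:::lattice_points(d3, phantom$truth$clean_series$spacing)
  pts <- pts[as.vector(mv > thr), , drop = FALSE]
  pts[seq(1, nrow(pts), by = thin), , drop = FALSE]
}
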