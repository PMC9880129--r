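# dcereg

Groupwise four-dimensional registration and perfusion analysis for
dynamic contrast-enhanced (DCE) breast MRI.

## What problem this solves

Breast DCE-MRI is read on subtraction images (postcontrast minus
unenhanced volume). Patient motion between time points creates
subtraction artifacts that can bury a lesion, and it corrupts voxel-wise
pharmacokinetic modeling. Conventional registration aligns volumes
pairwise to a chosen reference and treats contrast enhancement as a
nuisance; this package implements the alternative that the field has
converged on for dynamic data: align **all time points simultaneously**,
with a metric that separates physiological intensity change from
anatomical motion, so enhancement is retained while motion is removed.

It is written for image-analysis researchers working on DCE-MRI
preprocessing and for methodologists who need a fully controlled testbed
(known motion, known perfusion parameters) to quantify what a
registration step actually buys.

## The method

Each time point `g` gets its own cubic B-spline free-form deformation
`T_g(x) = x + u_g(x)`. Given N spatial samples intensity-sampled through
the current transforms into an N x G matrix, the metric is the
eigenvalue-compaction dissimilarity of the inter-timepoint correlation
matrix K (columns standardized):

    D = sum_{j=1..G} j * lambda_j,   lambda_1 >= ... >= lambda_G eig(K)

Aligned dynamic data are temporally low-rank (physiology only), so D is
small; motion disperses the spectrum into the heavily weighted trailing
eigenvalues. D is minimized by adaptive stochastic gradient descent with
an analytic gradient (eigenvalue perturbation chained through image
gradients and the B-spline basis), in a 4-level multi-resolution pyramid
(8/4/2/1-fold down-sampling), reference-free, with the mean displacement
over time points projected to zero (gauge fixing). Validation machinery:

- **Digital phantom** emulating the clinical protocol (6 time points:
  unenhanced, +90 s, then every 70 s; 0.7/0.7/2 mm voxels) with
  breast-like background, a Tofts-enhancing lesion, known smooth
  B-spline motion and noise.
- **Extended Tofts fitting** `C_t = vp*Cp + Ktrans * (Cp (*) exp(-kep t))`
  per voxel over a lesion ROI, with residual (RMSE) maps and
  percentile-wise residual analysis.
- **Semiautomatic segmentation** on subtraction images (spheroid brush,
  threshold at 0.1 of brush-max intensity, connected component, 3D
  morphology).
- **Assessment statistics**: NRS (0-10) motion scores folded into four
  categories, post-minus-pre deltas, sign test, exact Wilcoxon
  signed-rank, Spearman correlations, Kruskal-Wallis.

## Worked example

```r
library(dcereg)

# phantom with 4 mm smooth motion and 2% noise
cfg <- phantom_config(motion_mode = "bspline", motion_amplitude = 4,
                      noise_sigma = 0.02, seed = 0)
ph  <- generate_phantom(cfg)

reg <- register_groupwise(ph$series, registration_config(seed = 0))
reg
#> <groupwise_registration> 6 timepoints
#>   PCA2 metric: 6.159166 (unregistered) -> 6.034747 (registered)

model      <- rebase_model(reg$model, 1)   # into unenhanced geometry
registered <- resample_series(ph$series, model)

pre  <- fit_tofts_roi(ph$series,  ph$truth$lesion_mask)
post <- fit_tofts_roi(registered, ph$truth$lesion_mask)
da   <- delta_assessment(pre, post)
da
#> <case_assessment>
#>   delta ktrans mean: -0.08828, delta ktrans SD: -0.2685
#>   residual delta at p50: -0.003125, at p90: -0.006659
```

The PCA2 metric drops toward its aligned floor (G = 6 is the theoretical
minimum), and after registration the lesion's perfusion-model residuals
fall — more in the 90th percentile than the 50th (misalignment
concentrates in the high-error tail) — while the intralesion Ktrans
dispersion shrinks. Negative deltas mean motion reduction throughout.
`autoplot(da)` draws the per-percentile residual change;
`tidy(fit)`/`glance(fit)` give broom-style tables.

A thin CLI wrapping these functions ships in `inst/cli/dcereg`
(subcommands: `subtract`, `phantom`, `register`, `segment`, `fit`,
`assess`).

## Scientific scope

The phantom criteria demonstrate that the machinery behaves correctly
under known truth (motion recovered, metric compacted, residuals and
Ktrans dispersion reduced, no harm on motion-free data). They do not
reproduce clinical effect sizes, which derive from private patient data;
see the methods vignette (`vignettes/groupwise-dce-registration.Rmd`)
for the model, its assumptions, parameter defaults, and known
limitations.
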