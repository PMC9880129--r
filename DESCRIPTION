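Package: dcereg
Title: Groupwise Four-Dimensional Registration and Perfusion Analysis for
    Dynamic Contrast-Enhanced MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Groupwise, four-dimensional registration of dynamic
    contrast-enhanced (DCE) MRI series using a principal-component-analysis
    dissimilarity metric (eigenvalue compaction of the inter-timepoint
    intensity correlation matrix) optimized over per-timepoint cubic B-spline
    free-form deformations in a multi-resolution pyramid. Includes a digital
    breast-DCE phantom with known Tofts perfusion parameters and known
    motion, semiautomatic lesion segmentation on subtraction images,
    voxel-wise extended Tofts pharmacokinetic fitting with residual-error
    maps and percentile analysis, a numerical-ranking-scale motion grading
    model, and paired nonparametric statistics for quantifying the impact of
    registration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    tibble,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
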