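#' Plot residual change by intralesion percentile
#'
#' Visualizes where registration reduces perfusion-model misfit: the
#' post-minus-pre residual delta per intralesion percentile (negative bars
#' mean motion reduction, typically most pronounced in the high-error
#' tail).
#'
#' @param x a `case_assessment` from [delta_assessment()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.case_assessment <- function(x, ...) {
  ggplot2::ggplot(x$residuals,
                  ggplot2::aes(x = factor(.data$percentile),
                               y = .data$delta)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "intralesion residual percentile",
                  y = "residual change (post - pre)",
                  title = "Impact of registration on model residuals") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.case_assessment
#' @export
plot_residual_percentiles <- function(x, ...) autoplot.case_assessment(x, ...)

#' Plot a voxel-wise map slice with the ROI outline
#'
#' Quick-look display of one axial slice of a fitted parameter map.
#'
#' @param fit a `tofts_fit`.
#' @param map which map to show.
#' @param slice axial slice index; defaults to the ROI's central slice.
#' @return A ggplot object.
#' @export
plot_map_slice <- function(fit, map = c("ktrans", "residual", "ve", "vp"),
                           slice = NULL) {
  stopifnot(inherits(fit, "tofts_fit"))
  map <- match.arg(map)
  m <- fit[[map]]
  if (is.null(slice)) {
    zs <- which(fit$roi, arr.ind = TRUE)[, 3L]
    slice <- round(median(zs))
  }
  sl <- m[, , slice]
  df <- expand.grid(x = seq_len(nrow(sl)), y = seq_len(ncol(sl)))
  df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0(map, " map, slice ", slice)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
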