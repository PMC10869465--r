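#' Plot methods for specphen result objects
#'
#' `autoplot.corr_spectrum()` draws the correlation coefficient against
#' wavelength with significant runs shaded green. `autoplot.corr_heatmap()`
#' draws the split wavelength-pair heatmap: correlation coefficients in the
#' lower-left triangle, p-values in the upper-right. `autoplot.ndi_matrix()`
#' draws an NDI wavelength-pair heatmap.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name specphen-plots
NULL

#' @rdname specphen-plots
#' @export
autoplot.corr_spectrum <- function(object, ...) {
  runs <- attr(object, "runs")
  df <- as_tibble(unclass(object))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength_nm, y = .data$r))
  if (nrow(runs) > 0L) {
    p <- p + ggplot2::geom_rect(
      data = runs,
      ggplot2::aes(xmin = .data$lambda_start, xmax = .data$lambda_end),
      ymin = -1, ymax = 1, fill = "palegreen", alpha = 0.5,
      inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::labs(x = "Wavelength (nm)", y = "Pearson r") +
    ggplot2::theme_minimal()
}

#' @rdname specphen-plots
#' @export
autoplot.corr_heatmap <- function(object, ...) {
  df <- tidy(object)
  # r in the lower-left triangle (lambda1 > lambda2), p upper-right
  df$value <- ifelse(df$lambda1 > df$lambda2, df$r, df$p)
  df$panel <- ifelse(df$lambda1 > df$lambda2, "r", "p")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda2, y = .data$lambda1,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0, na.value = "grey90",
                                  name = "r / p") +
    ggplot2::labs(x = expression(lambda[2] ~ "(nm)"),
                  y = expression(lambda[1] ~ "(nm)")) +
    ggplot2::theme_minimal()
}

#' @rdname specphen-plots
#' @export
autoplot.ndi_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda2, y = .data$lambda1,
                                   fill = .data$ndi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0, limits = c(-1, 1),
                                  name = "NDI") +
    ggplot2::labs(x = expression(lambda[2] ~ "(nm)"),
                  y = expression(lambda[1] ~ "(nm)")) +
    ggplot2::theme_minimal()
}

#' Spectrum panel plot
#'
#' Line plot of reflectance spectra coloured by sample.
#'
#' @param spectra Long spectrum tibble (`sample_id`, `wavelength_nm`,
#'   `reflectance`).
#' @return A ggplot.
#' @export
plot_spectra <- function(spectra) {
  ggplot2::ggplot(spectra, ggplot2::aes(x = .data$wavelength_nm,
                                        y = .data$reflectance,
                                        colour = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "Wavelength (nm)", y = "Reflectance",
                  colour = "Sample") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
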