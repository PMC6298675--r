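# Plotting: base-graphics image display plus a ggplot2 autoplot for
# comparison tables (ggplot2 is suggested, not required).

#' Display a CT image or reconstruction
#'
#' Grayscale display with the package's axis convention (x = first index).
#'
#' @param image a `ct_image` or matrix.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @export
plot_image <- function(image, main = NULL, ...) {
  m <- as.matrix(image)
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                  col = grDevices::gray.colors(256, 0, 1),
                  asp = 1, xlab = "x (px)", ylab = "y (px)",
                  main = main, useRaster = TRUE, ...)
  invisible(image)
}

#' @export
plot.ct_image <- function(x, ...) plot_image(x, ...)

#' SNR-versus-views plot for a comparison table
#'
#' @param object a `ct_compare` tibble from [run_compare()].
#' @param ... ignored.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ct_compare <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    .stop_typed("tomowiener_dependency_error", "ggplot2 is required for autoplot")
  }
  ggplot2::ggplot(object,
                  ggplot2::aes(x = views, y = snr_db, colour = method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "projections", y = "SNR (dB)", colour = "method") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("views", "snr_db", "method"))
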