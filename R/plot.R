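#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

.field_df <- function(m, grid = NULL) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m))
  if (!is.null(grid)) {
    mm <- pixel_to_mm(grid, df$col, df$row)
    df$x_mm <- mm$x_mm; df$y_mm <- mm$y_mm
  } else {
    df$x_mm <- df$col; df$y_mm <- df$row
  }
  df
}

#' Plot a target model map
#'
#' @param object a \code{target_model_map}.
#' @param ... unused.
#' @return a ggplot of the target thickness field.
#' @method autoplot target_model_map
#' @export
autoplot.target_model_map <- function(object, ...) {
  df <- .field_df(object$thickness, object$grid)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "target\nthickness (mm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("Target model map (z = %g mm)", object$z_mm)) +
    ggplot2::theme_minimal()
}

#' Plot a reconstructed thickness map
#'
#' @param object a \code{recon_model_map}.
#' @param ... unused.
#' @return a ggplot of the printed thickness field.
#' @method autoplot recon_model_map
#' @export
autoplot.recon_model_map <- function(object, ...) {
  df <- .field_df(object$thickness, object$grid)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "printed\nthickness (mm)",
                                  na.value = "grey40") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("Reconstructed printed model (round %d)",
                                  object$round)) +
    ggplot2::theme_minimal()
}

#' Plot a defect characterization map with the standard legend colours
#'
#' @param object a \code{defect_map}.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot defect_map
#' @export
autoplot.defect_map <- function(object, ...) {
  dc <- defect_classes()
  df <- .field_df(object$labels, object$grid)
  df$class <- factor(dc$class[df$value + 1], levels = dc$class)
  pal <- stats::setNames(dc$color, dc$class)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = pal, name = "print state",
                               drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = "Defect characterization map") +
    ggplot2::theme_minimal()
}

#' Plot a per-pixel SSIM map
#'
#' @param object a \code{fidelity_result}.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fidelity_result
#' @export
autoplot.fidelity_result <- function(object, ...) {
  df <- .field_df(object$ssim_map)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "SSIM", limits = c(-1, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = sprintf("SSIM map (mean %.4f)", object$mean_ssim)) +
    ggplot2::theme_minimal()
}

#' Bar chart of per-layer fidelity
#'
#' @param series a [fidelity_series()].
#' @return a ggplot.
#' @export
plot_fidelity_series <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(factor(.data$layer), .data$mean_ssim)) +
    ggplot2::geom_col(fill = "#2C7FB8") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "layer / round", y = "mean SSIM (fidelity)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
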