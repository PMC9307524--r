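# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a B-scan as a gray-level raster
#'
#' Axial depth increases downward (row 1, the probe side, at the top), and
#' axes are in microns via the scan's pixel scales. Optionally overlays the
#' detected substrate line.
#'
#' @param object A [bscan()].
#' @param substrate_row Optional substrate row index to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.bscan <- function(object, substrate_row = NULL, ...) {
  img <- object$pixels
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$gray <- img[cbind(df$row, df$col)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col * object$lateral_scale,
                                        y = .data$row * object$axial_scale,
                                        fill = .data$gray)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "lateral position (µm)", y = "axial depth (µm)",
                  fill = "gray", title = object$id) +
    ggplot2::theme_minimal()
  if (!is.null(substrate_row)) {
    p <- p + ggplot2::geom_hline(yintercept = substrate_row * object$axial_scale,
                                 colour = "red", linetype = 2)
  }
  p
}

#' Plot a logistic growth fit over its data
#'
#' @param object A `logistic_fit` from [fit_logistic()].
#' @param ... Unused.
#' @return A ggplot of observations and, when converged, the fitted curve.
#' @exportS3Method ggplot2::autoplot
autoplot.logistic_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$time_h, y = .data$biomass)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (h)", y = "biomass") +
    ggplot2::theme_minimal()
  if (isTRUE(object$converged)) {
    tt <- seq(min(object$data$time_h), max(object$data$time_h), length.out = 200)
    curve_df <- tibble::tibble(
      time_h = tt,
      biomass = logistic_curve(tt, object$k_hat, object$K_hat, object$N0_hat))
    p <- p + ggplot2::geom_line(data = curve_df, colour = "steelblue")
  }
  p
}

#' Stacked relative-abundance composition profile
#'
#' @param table A count table (counts are converted to proportions) as used
#'   by [relative_abundance()].
#' @return A ggplot with one stacked bar per sample.
#' @export
plot_composition <- function(table) {
  relative_abundance(table) |>
    tidyr::pivot_longer(-"taxon", names_to = "sample",
                        values_to = "proportion") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$sample, y = .data$proportion,
                                 fill = .data$taxon)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "relative abundance", fill = "taxon") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Replicate-aggregated biofilm structure metrics
#'
#' @param analysis Output of [analyze_bscans()].
#' @return A ggplot of group means with one-standard-deviation error bars,
#'   facetted by metric.
#' @export
plot_structure_metrics <- function(analysis) {
  abort_if(!is.list(analysis) || is.null(analysis$aggregate),
           "`analysis` must be the output of analyze_bscans().")
  ggplot2::ggplot(analysis$aggregate,
                  ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
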