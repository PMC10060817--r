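#' Plot relative band power per ROI and condition
#'
#' Line chart of mean relative band power across the six bands, one
#' facet per ROI, coloured by condition.
#'
#' @param band_power_tbl the `band_power` table from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_band_power <- function(band_power_tbl) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the 'ggplot2' package", call. = FALSE)
  }
  agg <- stats::aggregate(power ~ roi + band + condition,
                          data = band_power_tbl, FUN = mean)
  agg$band <- factor(agg$band, levels = canonical_bands()$name)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$band, y = .data$power,
                                    colour = .data$condition,
                                    group = .data$condition)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~roi, ncol = 4) +
    ggplot2::labs(x = NULL, y = "relative band power") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Heatmap of a connectivity adjacency matrix
#'
#' @param m a `connectivity_matrix` or plain symmetric matrix.
#' @param title optional title.
#' @return A ggplot object.
#' @export
plot_adjacency <- function(m, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the 'ggplot2' package", call. = FALSE)
  }
  a <- if (inherits(m, "connectivity_matrix")) m$aecc else as.matrix(m)
  df <- expand.grid(roi_a = rownames(a), roi_b = colnames(a),
                    KEEP.OUT.ATTRS = FALSE)
  df$value <- as.vector(a)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$roi_a, y = .data$roi_b,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "AEC-c", title = title) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}
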