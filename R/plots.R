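#' Scatter plot of CDS versus mRNA fractal dimension
#'
#' The project-wide axis convention: x = mRNA FD, y = CDS FD. Points above
#' the identity line are pairs whose coding sequence is the more irregular
#' one. An optional [ols_fit()] line can be overlaid.
#'
#' @param rows A [compare_fd()] table.
#' @param fit Optional [ols_fit()] to draw.
#' @return A ggplot object.
#' @export
plot_fd_comparison <- function(rows, fit = NULL) {
  stopifnot(is.data.frame(rows), all(c("fd_mrna", "fd_cds") %in% names(rows)))
  p <- ggplot2::ggplot(rows, ggplot2::aes(x = .data$fd_mrna, y = .data$fd_cds)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "fractal dimension (mRNA)", y = "fractal dimension (CDS)",
      title = "CDS vs mRNA fractal dimension"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_abline(
      slope = fit$slope, intercept = fit$intercept, colour = "steelblue"
    )
  }
  p
}

#' @rdname fd_entropy_map
#' @param object An `fd_entropy_map` object (for `autoplot`).
#' @export
autoplot.fd_entropy_map <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fd, y = .data$entropy_bits)) +
    ggplot2::geom_abline(
      slope = object$fit$slope, intercept = object$fit$intercept,
      colour = "steelblue"
    ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$in_regression)) +
    ggplot2::scale_shape_manual(
      values = c(`TRUE` = 16, `FALSE` = 0),
      labels = c(`TRUE` = "in regression", `FALSE` = "designated outlier"),
      name = NULL
    ) +
    ggplot2::labs(
      x = "fractal dimension",
      y = sprintf("%snucleotide entropy (bits)", object$entropy_kind),
      title = "Fractal dimension vs entropy"
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of expression values per gene
#'
#' Faceted histograms of the expression distribution, the visual companion
#' to [expression_skewness()]: a long right tail corresponds to positive
#' skewness.
#'
#' @param table Long expression table (`gene`, `value`).
#' @param bins Histogram bins, default 30.
#' @return A ggplot object.
#' @export
plot_expression_distribution <- function(table, bins = 30) {
  stopifnot(is.data.frame(table), all(c("gene", "value") %in% names(table)))
  ggplot2::ggplot(table, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene), scales = "free_y") +
    ggplot2::labs(x = "expression z-score", y = "regions") +
    ggplot2::theme_minimal()
}
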