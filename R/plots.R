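#' Connectivity heat-map
#'
#' 8x8 tile map of group-mean band connectivity, sinks on rows and sources on
#' columns, diagonal zero, faceted by group. Mirrors the matrix heat-map
#' presentation of band-averaged PDC.
#'
#' @param conn Long connectivity tibble (`group`, `band`, `source`, `sink`,
#'   `pdc`).
#' @param band Band to display (default `"alpha"`).
#' @return A ggplot object.
#' @export
plot_connectivity <- function(conn, band = "alpha") {
  gm <- group_mean_matrices(conn, band)
  labels <- dmn_labels()
  gm$source <- factor(gm$source, levels = labels)
  gm$sink <- factor(gm$sink, levels = rev(labels))
  ggplot2::ggplot(gm, ggplot2::aes(x = .data$source, y = .data$sink,
                                   fill = .data$pdc)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_fill_gradient(
      low = "#2166ac", high = "#b2182b",
      name = "PDC",
      limits = c(0, max(gm$pdc)),
      labels = function(x) sprintf("%.3f", x)
    ) +
    ggplot2::labs(title = sprintf("Group-mean directed connectivity (%s band)", band),
                  x = "source", y = "sink") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.connectivity_tensor <- function(object, ...) {
  tb <- tidy(object, diagonal = TRUE)
  labels <- dimnames(object$values)[[1]]
  tb$source <- factor(tb$source, levels = labels)
  tb$sink <- factor(tb$sink, levels = rev(labels))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$source, y = .data$sink,
                                   fill = .data$pdc)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~band, nrow = 1) +
    ggplot2::scale_fill_gradient(low = "#2166ac", high = "#b2182b", name = "PDC") +
    ggplot2::labs(title = paste("Band-averaged PDC:", object$subject_id),
                  x = "source", y = "sink") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pdc_spectrum <- function(object, sources = NULL, sinks = NULL, ...) {
  tb <- tidy(object)
  if (!is.null(sources)) tb <- tb[tb$source %in% sources, ]
  if (!is.null(sinks)) tb <- tb[tb$sink %in% sinks, ]
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$freq, y = .data$pdc)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(sink ~ source) +
    ggplot2::labs(x = "frequency (Hz)", y = "PDC") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' SIAS-connectivity scatter plot
#'
#' Per-group scatter of subject mean band PDC against SIAS score with a linear
#' trend, the visual counterpart of [sias_correlation()].
#'
#' @param conn Long connectivity tibble.
#' @param subjects Subject tibble with `sias`.
#' @param band Band (default `"alpha"`).
#' @return A ggplot object.
#' @export
plot_sias_correlation <- function(conn, subjects, band = "alpha") {
  means <- subject_band_means(conn, band)
  df <- dplyr::inner_join(means, subjects[, c("subject_id", "sias")],
                          by = "subject_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_pdc, y = .data$sias)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "#b2182b") +
    ggplot2::facet_wrap(~group, scales = "free") +
    ggplot2::labs(x = sprintf("mean off-diagonal PDC (%s band)", band),
                  y = "SIAS score") +
    ggplot2::theme_minimal()
}
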