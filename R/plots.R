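# Biotype colors follow the field's usual coding for these arrays:
# miRNA red, snoRNA orange, tRF blue, other green, unknown gray.
BIOTYPE_COLORS <- c(miRNA = "#d7191c", snoRNA = "#fdae61", tRF = "#2c7bb6",
                    other = "#1a9641", snRNA = "#1a9641",
                    prediction = "#984ea3", unknown = "grey50",
                    spike = "grey30")

#' MA plot for one array
#'
#' @param ma M/A tibble ([compute_ma()] or normalized).
#' @param array array id to plot (default: first).
#' @return ggplot object.
#' @export
plot_ma <- function(ma, array = NULL) {
  if (is.null(array)) array <- ma$array_id[1]
  d <- dplyr::filter(ma, .data$array_id == array)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$A, y = .data$M)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_smooth(ggplot2::aes(group = .data$block),
                         method = "loess", formula = y ~ x, se = FALSE,
                         linewidth = 0.3, color = "red") +
    ggplot2::labs(title = array, x = "A (mean log2 intensity)",
                  y = "M (log2 ratio)")
}

#' Volcano plot of a DE table
#'
#' Dashed vertical lines mark a twofold change (|log2 FC| = 1; annotation
#' only, never a filter), the horizontal line the DE threshold on the
#' adjusted p-value.
#'
#' @param de DE tibble ([analyze_experiment()]`$de`).
#' @param threshold adjusted-p threshold drawn (default 0.05).
#' @return ggplot object.
#' @export
plot_volcano <- function(de, threshold = 0.05) {
  d <- dplyr::filter(de, !is.na(.data$p_adj))
  has_bio <- "biotype" %in% names(d)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc,
                                       y = -log10(.data$p_adj)))
  p <- if (has_bio) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$biotype),
                            alpha = 0.6, size = 0.8) +
      ggplot2::scale_color_manual(values = BIOTYPE_COLORS, na.value = "grey70")
  } else {
    p + ggplot2::geom_point(alpha = 0.5, size = 0.8)
  }
  p +
    ggplot2::geom_vline(xintercept = c(-1, 1), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = "dotted") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p")
}

#' Box plot of significant fold changes by biotype
#'
#' Log2 fold changes of DE-called candidates, color-coded by biotype;
#' whiskers extend to 1.5 IQR.
#'
#' @param de DE tibble with `biotype`.
#' @return ggplot object.
#' @export
plot_de_boxes <- function(de) {
  d <- dplyr::filter(de, .data$de_call)
  ggplot2::ggplot(d, ggplot2::aes(x = "", y = .data$log2fc)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_jitter(ggplot2::aes(color = .data$biotype), width = 0.15,
                         size = 1.5) +
    ggplot2::scale_color_manual(values = BIOTYPE_COLORS, na.value = "grey70") +
    ggplot2::labs(x = NULL, y = "log2 fold change (DE candidates)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano autoplot for an analysis result
#' @param object `ncarray_analysis`
#' @param ... passed to [plot_volcano()]
#' @return ggplot object
#' @method autoplot ncarray_analysis
#' @export
autoplot.ncarray_analysis <- function(object, ...) {
  plot_volcano(object$de, ...)
}
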