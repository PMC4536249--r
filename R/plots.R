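# ggplot2 views of the result tables.

#' Plot the PIC and major-allele-difference spectrum of a marker set
#'
#' @param object An `indel_markers` tibble.
#' @param bins Histogram bins for PIC.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot indel_markers
#' @export
autoplot.indel_markers <- function(object, bins = 20, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pic)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "grey20") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "polymorphism information content (PIC)",
                  y = "markers",
                  title = sprintf("%d InDel markers", nrow(df))) +
    ggplot2::theme_minimal()
}

#' Plot marker density along chromosomes
#'
#' @param markers Tibble with a `chrom` column (e.g. `indel_markers`).
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @return A ggplot of markers per kb by chromosome.
#' @export
plot_marker_density <- function(markers, chrom_lengths) {
  s <- summarize_chromosomes(markers, chrom_lengths)
  s <- s[s$chrom != "total", , drop = FALSE]
  ggplot2::ggplot(s, ggplot2::aes(x = .data$chrom, y = .data$density_per_kb)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::labs(x = NULL, y = "markers / kb") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a region summary table
#'
#' @param summary A [summarize_regions()] result.
#' @param y Which column to plot: density or proportion.
#' @return A ggplot.
#' @export
plot_region_summary <- function(summary,
                                y = c("density_per_kb", "proportion_pct")) {
  y <- match.arg(y)
  s <- summary[summary$category != "total", , drop = FALSE]
  s$category <- factor(s$category, levels = REGION_CATEGORIES)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$category, y = .data[[y]])) +
    ggplot2::geom_col(fill = "indianred3") +
    ggplot2::labs(x = NULL,
                  y = if (y == "density_per_kb") "items / kb" else "% of items") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
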