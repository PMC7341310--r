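# ggplot2 views of the main result types.

#' @importFrom ggplot2 ggplot aes geom_tile geom_col geom_point labs
#'   scale_fill_gradient2 theme_minimal theme element_text autoplot
NULL

#' Heatmap of sample correlations
#'
#' Tiles ordered by the dendrogram leaf order, so the clustering structure
#' (tissue first, then species, in well-behaved designs) is visible along
#' the diagonal.
#'
#' @param object A `sample_correlation` from [correlate_samples()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot sample_correlation
autoplot.sample_correlation <- function(object, ...) {
  ord <- object$leaf_order
  df <- as_tibble(as.data.frame.table(object$cor, responseName = "r")) |>
    mutate(Var1 = factor(.data$Var1, levels = ord),
           Var2 = factor(.data$Var2, levels = ord))
  ggplot(df, aes(x = .data$Var1, y = .data$Var2, fill = .data$r)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1), low = "#2166ac", mid = "white",
                         high = "#b2182b", midpoint = 0) +
    labs(x = NULL, y = NULL, fill = "Pearson r") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, hjust = 1, vjust = 0.5))
}

#' Bar chart of gene-action mode counts
#'
#' @param object A `mode_summary` from [summarize_modes()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot mode_summary
autoplot.mode_summary <- function(object, ...) {
  df <- tidy.mode_summary(object) |>
    mutate(mode = factor(.data$mode, levels = .data$mode))
  ggplot(df, aes(x = .data$mode, y = .data$n)) +
    geom_col(fill = "#4575b4") +
    labs(x = NULL, y = "features",
         title = sprintf("%d classified features", attr(object, "total_classified"))) +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 30, hjust = 1))
}

#' Volcano plot of a differential-expression comparison
#'
#' @param results Tibble from [test_de()] (after [call_degs()] the points
#'   are coloured by direction).
#' @param alpha,min_abs_log2fc Thresholds drawn as reference values.
#' @return A ggplot.
#' @export
plot_de_volcano <- function(results, alpha = 0.05, min_abs_log2fc = 1) {
  df <- results
  if (!"direction" %in% names(df)) {
    df <- call_degs(df, alpha = alpha, min_abs_log2fc = min_abs_log2fc)
  }
  ggplot(df, aes(x = .data$log2fc, y = -log10(pmax(.data$padj, 1e-300)),
                 colour = .data$direction)) +
    geom_point(size = 0.6, alpha = 0.6) +
    labs(x = "log2 fold change", y = "-log10 adjusted p", colour = NULL) +
    theme_minimal()
}
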