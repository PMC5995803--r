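#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_tile
#'   geom_hline geom_vline scale_color_manual labs facet_wrap theme_minimal
NULL

#' Volcano plot of a tested signature table
#'
#' Shrunken log2 fold change against -log10 adjusted p, with the
#' volcano-significant genes (adjusted p < `alpha`, fold change >=
#' `min_fc`) highlighted; faceted by cell type when several are present.
#'
#' @param object A signature tibble with `stat` and `adj_p` (enrichment or
#'   specificity rows).
#' @param alpha,min_fc Thresholds passed to [volcano_flags()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cellsig_signature <- function(object, alpha = 0.05, min_fc = 4, ...) {
  df <- object |>
    filter(.data$measure %in% c("enrichment", "specificity")) |>
    volcano_flags(alpha, min_fc)
  ggplot(df, aes(x = .data$stat, y = -log10(pmax(.data$adj_p, 1e-300)),
                 color = .data$flagged)) +
    geom_point(size = 0.6, alpha = 0.7) +
    geom_vline(xintercept = log2(min_fc), linetype = "dashed", linewidth = 0.3) +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed", linewidth = 0.3) +
    scale_color_manual(values = c(`FALSE` = "grey40", `TRUE` = "darkorange"),
                       guide = "none") +
    facet_wrap(~ cell_type + measure) +
    labs(x = "shrunken log2 fold change",
         y = expression(-log[10] ~ "adjusted p")) +
    theme_minimal()
}

#' @rdname autoplot.cellsig_signature
#' @export
plot_volcano <- function(object, alpha = 0.05, min_fc = 4) {
  autoplot.cellsig_signature(object, alpha = alpha, min_fc = min_fc)
}

#' Cumulative-marker correlation curve
#'
#' The SPV-vs-reference Spearman correlation as markers accumulate (red
#' line) over the correlations of each marker gene individually (black
#' dots).
#'
#' @param object A `cellsig_curve` from [cumulative_marker_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cellsig_curve <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$n_markers, y = .data$rho)) +
    geom_point(data = rename(object$gene_cor, n_markers = "rank"),
               color = "black", size = 1) +
    geom_line(color = "firebrick", linewidth = 0.8) +
    geom_hline(yintercept = 0, linetype = "dashed", linewidth = 0.3) +
    labs(x = "top marker genes used (cumulative)",
         y = "Spearman correlation with reference",
         title = object$cell_type) +
    theme_minimal()
}

#' Heatmap of a module-overlap matrix
#'
#' Tiles colored by -log10 BH-adjusted Fisher p, with significant pairs
#' outlined.
#'
#' @param object A `cellsig_module_overlap` from [module_overlap()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cellsig_module_overlap <- function(object, ...) {
  df <- object$pairs
  ggplot(df, aes(x = .data$module_b, y = .data$module_a,
                 fill = -log10(pmax(.data$adj_p, 1e-300)))) +
    geom_tile() +
    geom_point(data = filter(df, .data$significant), shape = 8, size = 1) +
    labs(x = "modules (network B)", y = "modules (network A)",
         fill = expression(-log[10] ~ "adj. p")) +
    theme_minimal()
}

#' Heatmap of surrogate proportion variables
#'
#' @param object A `cellsig_spv` from [estimate_proportions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cellsig_spv <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$cell_type, y = .data$sample_id,
                           fill = .data$spv)) +
    geom_tile() +
    labs(x = "cell type", y = "sample", fill = "SPV") +
    theme_minimal()
}
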