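#' Volcano plot of a paired differential-expression screen
#'
#' Log2 fold change against -log10 adjusted p-value, with the fold-change
#' and FDR thresholds drawn and points coloured by dysregulation call.
#'
#' @param object A [de_test()] result.
#' @param fdr,fc_up,fc_down Thresholds to draw (defaults match
#'   [de_test()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mirlink_de <- function(object, fdr = 0.05, fc_up = 1.50,
                                fc_down = 0.67, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = log2(.data$fold_change),
                               y = -log10(pmax(.data$p_adjusted, 1e-300)),
                               colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = log2(c(fc_down, fc_up)),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(fdr), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(up = "#d7301f", down = "#0570b0",
                                            none = "grey60")) +
    ggplot2::labs(x = "log2 fold change (tumor vs normal)",
                  y = "-log10 adjusted p",
                  colour = "direction",
                  title = unique(object$subgroup))
}

#' Association-screen overview plot
#'
#' Slope (beta) of each gene x miRNA association against -log10 gene-level
#' FDR p-value; significant tests are highlighted.
#'
#' @param object An [association_screen()] result.
#' @param fdr Threshold line to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mirlink_assoc <- function(object, fdr = 0.05, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$beta,
                               y = -log10(.data$p_fdr),
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(fdr), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d7301f",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "association slope (beta)", y = "-log10 FDR p",
                  colour = "significant")
}

#' Per-miRNA seed-match summary bar chart
#'
#' Numbers of associated genes with and without a seed-region match for
#' each miRNA, the graphical form of the per-miRNA summary table.
#'
#' @param summary Output of [summarize_by_mirna()].
#' @return A ggplot object.
#' @export
plot_seed_summary <- function(summary) {
  long <- summary |>
    select("mirna", with_match = "n_with_match",
           without_match = "n_without_match") |>
    tidyr::pivot_longer(-"mirna", names_to = "seed", values_to = "n_genes")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_genes,
                                     y = stats::reorder(.data$mirna, .data$n_genes,
                                                        FUN = sum),
                                     fill = .data$seed)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(with_match = "#31a354",
                                          without_match = "grey70")) +
    ggplot2::labs(x = "associated genes", y = NULL, fill = NULL)
}
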