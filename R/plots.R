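# ggplot2 views of the main result types.

#' Volcano plot of a case-vs-control comparison
#'
#' @param object An [lfq_compare()] result.
#' @param ... Unused.
#' @return A ggplot object: log2 fold change against -log10 adjusted p, with
#'   significant proteins highlighted.
#' @method autoplot lfq_comparison
#' @export
autoplot.lfq_comparison <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$log2_fold_change,
                               y = -log10(.data$p_adjusted),
                               colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(log[2] ~ "fold change (case - control)"),
                  y = expression(-log[10] ~ "adjusted p"),
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tile plot of a peptide-by-sample presence matrix
#'
#' @param presence A [presence_matrix()] result.
#' @return A ggplot object with detected cells marked.
#' @export
plot_presence_matrix <- function(presence) {
  long <- tidyr::pivot_longer(presence, -"peptide",
                              names_to = "sample", values_to = "detected")
  long$peptide <- factor(long$peptide, levels = rev(presence$peptide))
  long$sample <- factor(long$sample, levels = setdiff(names(presence), "peptide"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$peptide,
                                     fill = .data$detected)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey95", `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "detected") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Bar plot of family-level epitope conservation
#'
#' @param scan An [epitope_scan()] result.
#' @return A ggplot object of the perfect-match fraction per epitope.
#' @export
plot_epitope_conservation <- function(scan) {
  frac <- epitope_match_fraction(scan)
  ggplot2::ggplot(frac, ggplot2::aes(x = .data$epitope, y = 100 * .data$match_fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% loci with perfect epitope match") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}

#' Line plot of per-position identity along the reference ORF
#'
#' @param identity A [per_position_identity()] result.
#' @return A ggplot object.
#' @export
plot_position_identity <- function(identity) {
  ggplot2::ggplot(identity, ggplot2::aes(x = .data$position, y = .data$pct_identity)) +
    ggplot2::geom_line(colour = "grey30", linewidth = 0.3) +
    ggplot2::labs(x = "reference position (aa)", y = "% identity across loci") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}
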