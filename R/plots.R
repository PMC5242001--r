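#' Volcano plot of probe- or gene-level DE results
#'
#' Log fold change against -log10 nominal p, coloured by the volcano
#' classification (grey: not significant; black: p < 0.05; red: p < 0.05
#' and |logFC| > 1; green: FDR-adjusted p < 0.05 and |logFC| > 1), with
#' broken lines at the p and fold-change cutoffs.
#'
#' @param de DE tibble with `logFC`, `P.Value`, optionally `adj.P.Val`.
#' @param p_cutoff,lfc_cutoff Cutoffs passed to [classify_volcano()].
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, p_cutoff = 0.05, lfc_cutoff = 1) {
  d <- classify_volcano(de, p_cutoff, lfc_cutoff)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$logFC,
                                  y = -log10(.data$P.Value),
                                  colour = .data$volcano_class)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(p_cutoff), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-lfc_cutoff, lfc_cutoff),
                        linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(
      ns = "grey70", significant = "grey20",
      significant_high_fc = "red3", fdr_significant_high_fc = "green4"),
      drop = FALSE, name = NULL) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p-value") +
    ggplot2::theme_minimal()
}

#' Dot plot of a GO overrepresentation table
#'
#' Fold enrichment per category, point size by observed count, colour by
#' -log10 binomial p.
#'
#' @param enr Enrichment tibble from [run_enrichment()].
#' @param top Maximum number of rows to show.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enr, top = 25L) {
  d <- head(enr, top)
  d$term_name <- factor(d$term_name, levels = rev(d$term_name))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$FE, y = .data$term_name,
                                  size = .data$DE, colour = -log10(.data$P))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fold enrichment", y = NULL, size = "observed",
                  colour = "-log10 P") +
    ggplot2::theme_minimal()
}

#' Grouped bar chart of a GO-slim category profile
#'
#' Up- and down-regulated gene counts per category, the comparison drawn
#' for top gene lists across treatments or species.
#'
#' @param profile Tibble from [category_profile()], optionally with an
#'   added `label` column to facet several profiles.
#' @return A ggplot object.
#' @export
plot_category_profile <- function(profile) {
  d <- tidyr::pivot_longer(profile, c("n_up", "n_down"),
                           names_to = "direction", values_to = "n")
  d$direction <- factor(ifelse(d$direction == "n_up", "up", "down"),
                        levels = c("up", "down"))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$n,
                                       fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(up = "steelblue4", down = "indianred3")) +
    ggplot2::labs(x = NULL, y = "number of genes", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("label" %in% names(profile)) {
    p <- p + ggplot2::facet_wrap(~label)
  }
  p
}

#' Bar summary of a direction-split list overlap
#'
#' @param overlap Result of [venn_overlap()].
#' @return A ggplot object showing the seven partition counts.
#' @export
plot_overlap_counts <- function(overlap) {
  d <- overlap$counts
  d$section <- factor(d$section, levels = d$section)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$section, y = .data$n)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
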