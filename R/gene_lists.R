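#' Collapse probe-level results to a suggestive gene list
#'
#' Builds the final per-contrast gene list: uncharacterized probes (empty
#' gene symbol) are removed; among redundant probes sharing a gene symbol
#' the probe with the smallest nominal p-value represents the gene (ties
#' broken by larger absolute log fold change, then lexicographic probe id);
#' only genes with nominal p < `p_cutoff` are retained, the "suggestive"
#' criterion irrespective of multiple-testing correction. Genes with a log
#' fold change of exactly zero are excluded since no direction can be
#' assigned.
#'
#' @param de Probe-level DE tibble with columns `probe_id`, `logFC`,
#'   `P.Value` (optionally `adj.P.Val`, `perm_sig`).
#' @param probes Probe annotation tibble (`probe_id`, `gene_symbol`).
#' @param p_cutoff Nominal p-value cutoff (default 0.05).
#' @return A gene-list tibble: `gene`, `probe_id`, `logFC`, `P.Value`,
#'   direction `up`/`down`, plus any adjusted/permutation columns present.
#' @export
collapse_probes <- function(de, probes, p_cutoff = 0.05) {
  unknown <- setdiff(de$probe_id, probes$probe_id)
  if (length(unknown) > 0) {
    abort(sprintf("probe id(s) missing from the annotation: %s",
                  paste(head(unknown, 3), collapse = ", ")),
          class = "ovitx_consistency_error")
  }
  out <- select(de, -dplyr::any_of("gene"))
  out <- inner_join(out, select(probes, "probe_id", "gene_symbol"), by = "probe_id")
  out <- filter(out, .data$gene_symbol != "")
  out <- arrange(out, .data$P.Value, -abs(.data$logFC), .data$probe_id)
  out <- slice(group_by(out, .data$gene_symbol), 1L)
  out <- ungroup(out)
  out <- filter(out, .data$P.Value < p_cutoff, .data$logFC != 0)
  out <- mutate(out, direction = ifelse(.data$logFC > 0, "up", "down"))
  out <- rename(out, gene = "gene_symbol")
  arrange(select(out, "gene", dplyr::everything()), .data$gene)
}

#' Classify probes for a volcano plot
#'
#' Categories follow the conventional volcano legend: `ns`; `significant`
#' (nominal p < 0.05); `significant_high_fc` (additionally |logFC| > 1, the
#' red points); `fdr_significant_high_fc` (|logFC| > 1 at FDR-adjusted
#' p < 0.05, the green points). Fold-change units are log2.
#'
#' @param de DE tibble with `logFC`, `P.Value` and optionally `adj.P.Val`.
#' @param p_cutoff Nominal p cutoff (0.05).
#' @param lfc_cutoff Absolute log fold-change cutoff (1).
#' @return The tibble with a `volcano_class` factor column appended.
#' @export
classify_volcano <- function(de, p_cutoff = 0.05, lfc_cutoff = 1) {
  adj <- if ("adj.P.Val" %in% names(de)) de$adj.P.Val else rep(1, nrow(de))
  cls <- dplyr::case_when(
    adj < p_cutoff & abs(de$logFC) > lfc_cutoff ~ "fdr_significant_high_fc",
    de$P.Value < p_cutoff & abs(de$logFC) > lfc_cutoff ~ "significant_high_fc",
    de$P.Value < p_cutoff ~ "significant",
    TRUE ~ "ns"
  )
  mutate(de, volcano_class = factor(cls, levels = c(
    "ns", "significant", "significant_high_fc", "fdr_significant_high_fc")))
}

#' Direction-aware overlap of two gene lists
#'
#' Partitions the union of two per-contrast gene lists on gene symbols,
#' separately within the up- and down-regulated directions, as drawn in a
#' pair of direction-split Venn diagrams: genes private to either list,
#' genes common with concordant direction, and genes present in both lists
#' with opposite directions (reported separately as `discordant`, excluded
#' from the common counts).
#'
#' @param list_a,list_b Gene-list tibbles from [collapse_probes()] (columns
#'   `gene`, `direction`).
#' @return A named list of character vectors: `a_only_up`, `a_only_down`,
#'   `common_up`, `common_down`, `b_only_up`, `b_only_down`, `discordant`,
#'   plus a `counts` tibble.
#' @export
venn_overlap <- function(list_a, list_b) {
  a_up <- list_a$gene[list_a$direction == "up"]
  a_dn <- list_a$gene[list_a$direction == "down"]
  b_up <- list_b$gene[list_b$direction == "up"]
  b_dn <- list_b$gene[list_b$direction == "down"]
  b_all <- c(b_up, b_dn)
  a_all <- c(a_up, a_dn)
  out <- list(
    a_only_up = sort(setdiff(a_up, b_all)),
    a_only_down = sort(setdiff(a_dn, b_all)),
    common_up = sort(intersect(a_up, b_up)),
    common_down = sort(intersect(a_dn, b_dn)),
    b_only_up = sort(setdiff(b_up, a_all)),
    b_only_down = sort(setdiff(b_dn, a_all)),
    discordant = sort(union(intersect(a_up, b_dn), intersect(a_dn, b_up)))
  )
  out$counts <- tibble(section = names(out)[1:7],
                       n = vapply(out[1:7], length, integer(1)))
  out
}

#' Select the top genes by log fold change
#'
#' The `n_up` genes with the largest and `n_down` genes with the most
#' negative log fold changes among an already p-filtered list (the
#' "top 200" selection when both are 100). If fewer genes exist in a
#' direction, all are returned. Ties at the cut are broken by smaller
#' p-value, then lexicographic gene symbol, so the selection is
#' deterministic.
#'
#' @param gene_list Gene-list tibble (`gene`, `logFC`, `P.Value`,
#'   `direction`), already filtered at nominal p < 0.05.
#' @param n_up,n_down Number of up- and down-regulated genes to keep.
#' @return The selected subset, up-regulated genes first in descending
#'   logFC, then down-regulated in ascending logFC.
#' @export
top_n_by_lfc <- function(gene_list, n_up = 100L, n_down = 100L) {
  up <- filter(gene_list, .data$direction == "up")
  up <- arrange(up, desc(.data$logFC), .data$P.Value, .data$gene)
  up <- head(up, n_up)
  dn <- filter(gene_list, .data$direction == "down")
  dn <- arrange(dn, .data$logFC, .data$P.Value, .data$gene)
  dn <- head(dn, n_down)
  bind_rows(up, dn)
}
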