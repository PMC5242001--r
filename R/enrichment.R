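#' A GO annotation universe with a fixed reference size
#'
#' Couples a gene-to-term annotation table with the total number of
#' reference genes `n_ref` used as the denominator of the
#' overrepresentation test. Genes without annotation count toward the
#' universe but belong to no category, which is how a list is tested
#' against a genome-wide reference gene count (e.g. 15,789 for chicken or
#' 21,398 for pig).
#'
#' @param annotation Tibble with columns `gene`, `term` and optionally
#'   `term_name`.
#' @param n_ref Total reference universe size; must be at least the number
#'   of distinct annotated genes.
#' @param genes Optional explicit universe membership (character vector of
#'   length `n_ref`); when supplied, list genes are matched against it.
#' @return A `go_universe` object.
#' @export
go_universe <- function(annotation, n_ref, genes = NULL) {
  n_ref <- as.integer(n_ref)
  annotation <- as_tibble(annotation)
  if (nrow(annotation) > 0 && !"term_name" %in% names(annotation)) {
    annotation$term_name <- annotation$term
  }
  n_annotated <- length(unique(annotation$gene))
  if (n_ref < n_annotated) {
    abort(sprintf(
      "n_ref (%d) is smaller than the number of distinct annotated genes (%d)",
      n_ref, n_annotated), class = "ovitx_consistency_error")
  }
  if (!is.null(genes)) {
    if (length(genes) != n_ref) {
      abort("length(genes) must equal n_ref", class = "ovitx_consistency_error")
    }
    if (!all(annotation$gene %in% genes)) {
      abort("annotated genes missing from the explicit universe",
            class = "ovitx_consistency_error")
    }
  }
  structure(list(annotation = annotation, n_ref = n_ref, genes = genes),
            class = "go_universe")
}

#' @export
print.go_universe <- function(x, ...) {
  cat(sprintf("<go_universe> %d reference genes, %d terms, %d annotated genes\n",
              x$n_ref, length(unique(x$annotation$term)),
              length(unique(x$annotation$gene))))
  invisible(x)
}

#' Per-term REF counts of a universe
#'
#' @param universe A [go_universe].
#' @return A tibble with columns `term`, `term_name`, `REF`.
#' @export
term_ref_counts <- function(universe) {
  if (nrow(universe$annotation) == 0) {
    return(tibble(term = character(), term_name = character(), REF = integer()))
  }
  summarise(group_by(universe$annotation, .data$term, .data$term_name),
            REF = dplyr::n_distinct(.data$gene), .groups = "drop")
}

#' Expected category count in a gene list
#'
#' `EXPC = n_list * REF / N_ref`: the number of list genes expected in a
#' category of size `REF` if the list were drawn at random from a universe
#' of `N_ref` genes.
#'
#' @param ref Category size in the universe (REF).
#' @param n_list Number of (annotated) genes in the list.
#' @param n_ref Universe size.
#' @return The expected count.
#' @export
#' @examples
#' expected_count(498, 221, 15789)  # 6.97
expected_count <- function(ref, n_list, n_ref) {
  if (any(n_ref == 0)) abort("N_ref must be positive", class = "ovitx_input_error")
  if (any(ref > n_ref) || any(n_list > n_ref)) {
    abort("REF and n_list cannot exceed N_ref", class = "ovitx_input_error")
  }
  n_list * ref / n_ref
}

#' Fold enrichment
#'
#' Observed over expected category count; `NA` when the expected count is
#' zero.
#'
#' @param observed Observed number of list genes in the category.
#' @param expc Expected count from [expected_count()].
#' @return `observed / expc`, or `NA` where `expc` is 0.
#' @export
fold_enrichment <- function(observed, expc) {
  ifelse(expc > 0, observed / expc, NA_real_)
}

#' One-sided binomial overrepresentation p-value
#'
#' Exact binomial tail for the number of category genes in a list of
#' `n_list` draws with per-draw category probability `p_cat = REF / N_ref`:
#' over-representation tests `P(X >= observed)`, under-representation
#' `P(X <= observed)`, computed through the stable cumulative/survival
#' forms of [stats::pbinom()].
#'
#' @param observed Observed count (0 to `n_list`).
#' @param n_list List size.
#' @param p_cat Category probability in `(0, 1)`.
#' @param sign `"over"` or `"under"`.
#' @return The tail probability.
#' @export
#' @examples
#' binomial_overrep_p(1, 221, 2 / 15789, "over")  # 2.76e-02
binomial_overrep_p <- function(observed, n_list, p_cat, sign = c("over", "under")) {
  sign <- match.arg(sign)
  if (any(p_cat <= 0) || any(p_cat >= 1)) {
    abort("p_cat must lie in (0, 1)", class = "ovitx_input_error")
  }
  if (any(observed > n_list) || any(observed < 0)) {
    abort("observed must lie in [0, n_list]", class = "ovitx_input_error")
  }
  if (sign == "over") {
    pbinom(observed - 1, n_list, p_cat, lower.tail = FALSE)
  } else {
    pbinom(observed, n_list, p_cat)
  }
}

#' PANTHER-style GO overrepresentation test
#'
#' For every annotated category: REF (category size in the universe), the
#' observed number of list genes, the expected count, the fold enrichment,
#' the over/under sign (`+` when observed >= expected) and the one-sided
#' binomial tail probability on the matching side. List genes absent from
#' the annotated universe are dropped from `n_list` (the list size reported
#' is the annotated-list size) and their count recorded in attribute
#' `"n_dropped"`. Rows with `REF > 0` and `P < alpha` are returned, sorted
#' by descending fold enrichment then ascending p-value.
#'
#' @param genes Character vector of gene symbols, or a gene-list tibble with
#'   a `gene` column.
#' @param universe A [go_universe].
#' @param alpha Reporting cutoff on the raw binomial p-value (no
#'   multiple-testing correction is applied, matching raw `P < 0.05`
#'   reporting).
#' @return A tibble with columns `term`, `term_name`, `REF`, `DE`, `EXPC`,
#'   `FE`, `sign`, `P`; attributes `"n_list"` and `"n_dropped"`.
#' @export
#' @examples
#' u <- generate_annotation_universe(
#'   1000, data.frame(term = "GO:0000001", ref = 40), seed = 1)
#' hits <- u$annotation$gene[1:10]
#' run_enrichment(hits, u, alpha = 1)
run_enrichment <- function(genes, universe, alpha = 0.05) {
  if (is.data.frame(genes)) genes <- genes$gene
  genes <- unique(genes)
  if (!inherits(universe, "go_universe")) {
    abort("universe must be a go_universe", class = "ovitx_input_error")
  }
  if (universe$n_ref == 0 ||
      (nrow(universe$annotation) == 0 && is.null(universe$genes))) {
    abort("empty universe", class = "ovitx_input_error")
  }
  members <- universe$genes %||% unique(universe$annotation$gene)
  in_universe <- genes %in% members
  n_dropped <- sum(!in_universe)
  if (n_dropped > 0) {
    inform(sprintf("%d list gene(s) absent from the universe were dropped",
                   n_dropped))
  }
  genes <- genes[in_universe]
  n_list <- length(genes)

  refs <- term_ref_counts(universe)
  if (nrow(refs) == 0 || n_list == 0) {
    out <- tibble(term = character(), term_name = character(), REF = integer(),
                  DE = integer(), EXPC = numeric(), FE = numeric(),
                  sign = character(), P = numeric())
    attr(out, "n_list") <- n_list
    attr(out, "n_dropped") <- n_dropped
    return(out)
  }
  obs_tbl <- summarise(
    group_by(filter(universe$annotation, .data$gene %in% genes), .data$term),
    DE = dplyr::n_distinct(.data$gene), .groups = "drop")
  out <- left_join(refs, obs_tbl, by = "term")
  out <- mutate(out,
    DE = ifelse(is.na(.data$DE), 0L, .data$DE),
    EXPC = expected_count(.data$REF, n_list, universe$n_ref),
    FE = fold_enrichment(.data$DE, .data$EXPC),
    sign = ifelse(.data$DE >= .data$EXPC, "+", "-"),
    P = ifelse(.data$sign == "+",
               binomial_overrep_p(.data$DE, n_list, .data$REF / universe$n_ref, "over"),
               binomial_overrep_p(.data$DE, n_list, .data$REF / universe$n_ref, "under")))
  out <- filter(out, .data$REF > 0, .data$P < alpha)
  out <- arrange(out, desc(.data$FE), .data$P, .data$term)
  attr(out, "n_list") <- n_list
  attr(out, "n_dropped") <- n_dropped
  out
}
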