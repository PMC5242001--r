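#' Read a probe-level expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds probe identifiers
#' and whose header row names the samples; decimal point `.`, no missing
#' values, no quoting. The file round-trips bit-exactly through
#' [write_expression_matrix()], preserving row and column order.
#'
#' @param path Path to the TSV file.
#' @return A tibble: `probe_id` plus one numeric column per sample.
#' @export
read_expression_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1) abort("empty expression file", class = "ovitx_format_error")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  if (anyDuplicated(samples)) {
    abort(sprintf("duplicate sample id '%s'", samples[duplicated(samples)][1L]),
          class = "ovitx_format_error")
  }
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  widths <- lengths(body)
  if (any(widths != length(header))) {
    abort(sprintf("ragged row %d: expected %d fields, found %d",
                  which(widths != length(header))[1L] + 1L, length(header),
                  widths[widths != length(header)][1L]),
          class = "ovitx_format_error")
  }
  ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate probe id '%s'", ids[duplicated(ids)][1L]),
          class = "ovitx_format_error")
  }
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(samples))
  for (j in seq_along(samples)) {
    col <- vapply(body, `[[`, character(1), j + 1L)
    num <- suppressWarnings(as.numeric(col))
    if (anyNA(num)) {
      i <- which(is.na(num))[1L]
      abort(sprintf("non-numeric value '%s' at row %d, column '%s'",
                    col[i], i + 1L, samples[j]),
            class = "ovitx_format_error")
    }
    vals[, j] <- num
  }
  colnames(vals) <- samples
  bind_cols(tibble(probe_id = ids), as_tibble(vals))
}

#' Write an expression matrix to TSV
#'
#' Deterministic writer: fixed column order, `%.17g` number formatting, so
#' the same table always produces byte-identical files and values survive a
#' write/read round trip exactly.
#'
#' @param tbl Expression tibble (`probe_id` + sample columns).
#' @param path Output path.
#' @param id_name Header used for the identifier column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(tbl, path, id_name = names(tbl)[1L]) {
  m <- expr_to_matrix(tbl)
  header <- paste(c(id_name, colnames(m)), collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format_full(m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read or write the sample design table
#'
#' Two-column TSV, `sample` and `group`, one row per array.
#'
#' @param path File path.
#' @return `read_design()` returns a tibble with columns `sample`, `group`.
#' @export
read_design <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (!all(c("sample", "group") %in% names(d))) {
    abort("design file must have columns 'sample' and 'group'",
          class = "ovitx_format_error")
  }
  if (anyDuplicated(d$sample)) {
    abort("duplicate sample in design file", class = "ovitx_format_error")
  }
  as_tibble(d[, c("sample", "group")])
}

#' @param design Design tibble.
#' @rdname read_design
#' @export
write_design <- function(design, path) {
  writeLines(c("sample\tgroup", paste(design$sample, design$group, sep = "\t")),
             path, useBytes = TRUE)
  invisible(path)
}

#' Read or write the probe annotation table
#'
#' TSV with columns `probe_id` and `gene_symbol`; an empty symbol marks an
#' uncharacterized probe. The `characterized` flag is derived: it is `FALSE`
#' exactly when the symbol is empty.
#'
#' @param path File path.
#' @return A tibble with columns `probe_id`, `gene_symbol`, `characterized`.
#' @export
read_probe_annotation <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE, na = character())
  if (!all(c("probe_id", "gene_symbol") %in% names(d))) {
    abort("probe file must have columns 'probe_id' and 'gene_symbol'",
          class = "ovitx_format_error")
  }
  if (anyDuplicated(d$probe_id)) {
    abort("duplicate probe_id in probe annotation", class = "ovitx_format_error")
  }
  mutate(as_tibble(d[, c("probe_id", "gene_symbol")]),
         gene_symbol = ifelse(is.na(.data$gene_symbol), "", .data$gene_symbol),
         characterized = .data$gene_symbol != "")
}

#' @param probes Probe annotation tibble.
#' @rdname read_probe_annotation
#' @export
write_probe_annotation <- function(probes, path) {
  writeLines(c("probe_id\tgene_symbol",
               paste(probes$probe_id, probes$gene_symbol, sep = "\t")),
             path, useBytes = TRUE)
  invisible(path)
}

#' Read a gene-to-GO annotation table with a fixed reference universe size
#'
#' TSV with columns `gene` and `term` (optionally `term_name`), one row per
#' gene/term pair. The universe size is fixed to `n_ref`: genes without any
#' annotation are counted in the universe but belong to no category, which
#' matches the convention of testing a list against a genome-wide reference
#' gene count.
#'
#' @param path File path.
#' @param n_ref Total number of genes in the reference universe; must be at
#'   least the number of distinct annotated genes.
#' @return A [go_universe] object.
#' @export
read_go_annotation <- function(path, n_ref) {
  d <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (nrow(d) == 0 || ncol(d) == 0) {
    return(go_universe(tibble(gene = character(), term = character(),
                              term_name = character()), n_ref))
  }
  if (!all(c("gene", "term") %in% names(d))) {
    abort("GO annotation file must have columns 'gene' and 'term'",
          class = "ovitx_format_error")
  }
  if (!"term_name" %in% names(d)) d$term_name <- d$term
  go_universe(as_tibble(d[, c("gene", "term", "term_name")]), n_ref)
}

#' @param universe A [go_universe].
#' @rdname read_go_annotation
#' @export
write_go_annotation <- function(universe, path) {
  a <- universe$annotation
  writeLines(c("gene\tterm\tterm_name",
               paste(a$gene, a$term, a$term_name, sep = "\t")),
             path, useBytes = TRUE)
  invisible(path)
}

#' Read a gene-family mapping table
#'
#' TSV with columns `gene` and `family`, used by [shared_families()] for
#' cross-species comparison of curated functional families.
#'
#' @param path File path.
#' @return A tibble with columns `gene`, `family`.
#' @export
read_family_map <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (!all(c("gene", "family") %in% names(d))) {
    abort("family file must have columns 'gene' and 'family'",
          class = "ovitx_format_error")
  }
  as_tibble(d[, c("gene", "family")])
}

#' Write a differential-expression results table
#'
#' Deterministic TSV writer mirroring the column layout
#' `gene, logFC, t, P.Value, adj.P.Val, perm_sig`: statistics at 6
#' significant digits, p-values in E-notation with 3 significant digits.
#'
#' @param de DE results tibble (probe- or gene-level).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  id_col <- if ("gene" %in% names(de)) "gene" else "probe_id"
  cols <- c(id_col, "logFC", "t", "P.Value", "adj.P.Val", "perm_sig")
  cols <- cols[cols %in% names(de)]
  body <- vapply(seq_len(nrow(de)), function(i) {
    row <- vapply(cols, function(cn) {
      v <- de[[cn]][i]
      if (cn %in% c("P.Value", "adj.P.Val")) format_pvalue(v)
      else if (cn %in% c("logFC", "t")) format_stat(v)
      else as.character(v)
    }, character(1))
    paste(row, collapse = "\t")
  }, character(1))
  writeLines(c(paste(cols, collapse = "\t"), body), path, useBytes = TRUE)
  invisible(path)
}

#' Write a GO overrepresentation table
#'
#' Columns mirror a PANTHER-style report: term, term name, REF (category
#' size in the universe), DE (observed count in the list), EXPC (expected
#' count), FE (fold enrichment), sign (+/-), P (binomial tail, E-notation,
#' 3 significant digits).
#'
#' @param enr Enrichment tibble from [run_enrichment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_table <- function(enr, path) {
  body <- vapply(seq_len(nrow(enr)), function(i) {
    paste(c(enr$term[i], enr$term_name[i], enr$REF[i], enr$DE[i],
            sprintf("%.2f", enr$EXPC[i]),
            ifelse(is.na(enr$FE[i]), "NA", sprintf("%.2f", enr$FE[i])),
            enr$sign[i], format_pvalue(enr$P[i])),
          collapse = "\t")
  }, character(1))
  writeLines(c("term\tterm_name\tREF\tDE\tEXPC\tFE\tsign\tP", body), path,
             useBytes = TRUE)
  invisible(path)
}

#' Read a run configuration from a YAML key/value file
#'
#' Keys mirror the arguments of [simulation_config()]; unknown keys raise an
#' error so typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A [simulation_config()].
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration keys: %s", paste(unknown, collapse = ", ")),
          class = "ovitx_config_error")
  }
  if (!is.null(vals$group_sizes)) vals$group_sizes <- unlist(vals$group_sizes)
  do.call(simulation_config, vals)
}
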