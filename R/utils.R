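#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   across left_join inner_join anti_join semi_join bind_rows bind_cols
#'   distinct pull rename n slice row_number desc
#' @importFrom stats median sd var density dnorm pnorm pt pbinom qnorm rnorm
#'   runif rchisq setNames p.adjust integrate
#' @importFrom utils combn head
NULL

# Convert a wide expression tibble (id column + one numeric column per sample)
# to a numeric matrix with ids as rownames.
expr_to_matrix <- function(tbl, id_col = 1L) {
  ids <- tbl[[id_col]]
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    abort(sprintf("duplicate identifier '%s' in expression table", dup),
          class = "ovitx_format_error")
  }
  m <- as.matrix(tbl[, -id_col, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- colnames(tbl[, -id_col])[!vapply(tbl[, -id_col], is.numeric, logical(1))][1L]
    abort(sprintf("non-numeric values in sample column '%s'", bad),
          class = "ovitx_format_error")
  }
  rownames(m) <- ids
  m
}

matrix_to_expr <- function(m, id_name = "probe_id") {
  out <- as_tibble(m)
  out <- bind_cols(tibble(!!id_name := rownames(m)), out)
  out
}

# Validate a design tibble against sample columns of an expression table.
check_design <- function(design, sample_ids) {
  if (!all(c("sample", "group") %in% names(design))) {
    abort("design must have columns 'sample' and 'group'", class = "ovitx_design_error")
  }
  missing <- setdiff(sample_ids, design$sample)
  if (length(missing) > 0) {
    abort(sprintf("samples without a group label: %s",
                  paste(missing, collapse = ", ")),
          class = "ovitx_design_error")
  }
  invisible(design)
}

group_of <- function(design, samples) {
  design$group[match(samples, design$sample)]
}

# Deterministic number formatting used by the table writers: 6 significant
# digits for statistics, E-notation with 3 significant digits for p-values.
format_stat <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.6g", x))
}

format_pvalue <- function(p) {
  ifelse(is.na(p), "NA", sprintf("%.2E", p))
}

# Full-precision formatting for matrices so write/read round-trips are exact.
format_full <- function(x) sprintf("%.17g", x)
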