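#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: sort ascending, `q_i = min_{j >= i} (m p_j / j)`
#' capped at 1, returned in the original order.
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]", class = "ovitx_input_error")
  }
  p.adjust(p, method = "BH")
}

#' Configuration of the permutation experiment-wide threshold
#'
#' Houses the knobs of the permutation procedure: `n_perm` label shufflings
#' (1,000 by default), retention of the p-value at the `top_frac` rank of
#' each permutation's sorted p-values (top 1% by default), and the
#' `threshold_quantile` (5% by default) across permutations defining the
#' experiment-wide cutoff. With a 4-vs-4 contrast only `choose(8, 4) = 70`
#' distinct label assignments exist, so by default all distinct assignments
#' (minus the identity) are enumerated exactly once instead of sampled.
#'
#' @param n_perm Number of permutations when sampling.
#' @param top_frac Fraction of genes defining the retained rank per
#'   permutation.
#' @param threshold_quantile Quantile (small end) of the retained values
#'   used as the threshold.
#' @param seed Integer seed for sampled permutations.
#' @param enumerate_if_fewer Enumerate all distinct assignments when fewer
#'   than `n_perm` exist.
#' @return A `permutation_config` list.
#' @export
permutation_config <- function(n_perm = 1000L, top_frac = 0.01,
                               threshold_quantile = 0.05, seed = 1L,
                               enumerate_if_fewer = TRUE) {
  if (n_perm < 1) abort("n_perm must be >= 1", class = "ovitx_config_error")
  if (top_frac <= 0 || top_frac >= 1) {
    abort("top_frac must lie in (0, 1)", class = "ovitx_config_error")
  }
  if (threshold_quantile <= 0 || threshold_quantile >= 1) {
    abort("threshold_quantile must lie in (0, 1)", class = "ovitx_config_error")
  }
  structure(list(n_perm = as.integer(n_perm), top_frac = top_frac,
                 threshold_quantile = threshold_quantile, seed = as.integer(seed),
                 enumerate_if_fewer = isTRUE(enumerate_if_fewer)),
            class = "permutation_config")
}

#' Permutation-based experiment-wide significance threshold
#'
#' For each permutation the group labels of the contrast's samples are
#' shuffled, the full linear-model and empirical-Bayes pipeline is re-run
#' (the variance prior re-estimated inside the permutation), nominal
#' p-values are computed for all G genes, and the p-value at rank
#' `ceiling(top_frac * G)` from the smallest is retained. The threshold is
#' the value at rank `ceiling(threshold_quantile * B)` from the smallest
#' among the B retained values (nearest-rank convention, no interpolation);
#' on the evidence scale that is the top 5% of the per-permutation top-1%
#' statistics. Genes whose observed nominal p-value falls strictly below
#' the threshold are experiment-wide significant.
#'
#' When `enumerate_if_fewer` is set and fewer distinct label assignments
#' exist than `n_perm`, every distinct assignment except the identity is
#' used exactly once; otherwise assignments are sampled with replacement
#' under the configured seed.
#'
#' @param expr Normalized log2 expression tibble (gene or probe level).
#' @param design Design tibble (`sample`, `group`).
#' @param contrast Character vector `c(treatment, reference)`.
#' @param cfg A [permutation_config()].
#' @return A `perm_threshold` object: `threshold`, the sorted `retained`
#'   values, the number of permutations `n_perm`, and whether assignments
#'   were enumerated.
#' @export
permutation_threshold <- function(expr, design, contrast,
                                  cfg = permutation_config()) {
  m <- expr_to_matrix(expr)
  check_design(design, colnames(m))
  grp <- group_of(design, colnames(m))
  in_contrast <- which(grp %in% contrast)
  n_t <- sum(grp == contrast[1])
  n_r <- sum(grp == contrast[2])
  if (n_t < 2 || n_r < 2) {
    abort("each contrast group needs at least 2 samples", class = "ovitx_design_error")
  }
  n_c <- n_t + n_r
  n_distinct <- choose(n_c, n_t)
  if (n_distinct < 2) {
    abort("fewer than 2 distinct label assignments possible",
          class = "ovitx_design_error")
  }

  observed_t <- which(grp[in_contrast] == contrast[1])
  if (cfg$enumerate_if_fewer && n_distinct <= cfg$n_perm) {
    all_assign <- combn(n_c, n_t, simplify = FALSE)
    identity <- vapply(all_assign, function(a) identical(a, observed_t), logical(1))
    assignments <- all_assign[!identity]
    enumerated <- TRUE
  } else {
    withr::local_seed(cfg$seed)
    assignments <- replicate(cfg$n_perm, sort(sample.int(n_c, n_t)),
                             simplify = FALSE)
    enumerated <- FALSE
  }

  G <- nrow(m)
  rank_keep <- ceiling(cfg$top_frac * G)
  retained <- vapply(assignments, function(a) {
    g2 <- grp
    g2[in_contrast] <- contrast[2]
    g2[in_contrast[a]] <- contrast[1]
    p <- null_pipeline_p(m, g2, contrast)
    sort(p, partial = rank_keep)[rank_keep]
  }, numeric(1))

  B <- length(retained)
  rank_thr <- ceiling(cfg$threshold_quantile * B)
  retained_sorted <- sort(retained)
  structure(list(
    threshold = retained_sorted[rank_thr],
    retained = retained_sorted,
    n_perm = B,
    enumerated = enumerated,
    contrast = paste(contrast, collapse = "_vs_"),
    config = cfg
  ), class = "perm_threshold")
}

# Full linear-model + eBayes pipeline on a matrix with given group labels,
# returning nominal p-values for the contrast. Used inside permutations.
null_pipeline_p <- function(m, grp, contrast) {
  groups <- unique(grp)
  ind <- outer(grp, groups, "==") * 1
  counts <- colSums(ind)
  means <- m %*% sweep(ind, 2, counts, "/")
  colnames(means) <- groups
  fitted <- means[, match(grp, groups), drop = FALSE]
  d_g <- ncol(m) - length(groups)
  s2 <- rowSums((m - fitted)^2) / d_g
  prior <- estimate_prior(s2, d_g)
  d0 <- prior$d0
  s2_tilde <- if (is.infinite(d0)) rep(prior$s2_0, length(s2))
              else (d0 * prior$s2_0 + d_g * s2) / (d0 + d_g)
  n_t <- counts[[which(groups == contrast[1])]]
  n_r <- counts[[which(groups == contrast[2])]]
  beta <- means[, contrast[1]] - means[, contrast[2]]
  se <- sqrt(s2_tilde * (1 / n_t + 1 / n_r))
  t_tilde <- ifelse(se > 0, beta / se, 0)
  2 * pt(-abs(t_tilde), df = d0 + d_g)
}

#' @export
print.perm_threshold <- function(x, ...) {
  cat(sprintf("<perm_threshold> %s: threshold = %.3g (%d %s permutations)\n",
              x$contrast, x$threshold, x$n_perm,
              if (x$enumerated) "enumerated" else "sampled"))
  invisible(x)
}

#' Flag experiment-wide significant genes
#'
#' Adds a logical `perm_sig` column: nominal p-value strictly below the
#' permutation threshold.
#'
#' @param de DE results tibble with a `P.Value` column.
#' @param threshold A `perm_threshold` object or a bare numeric cutoff.
#' @return The tibble with a `perm_sig` column appended.
#' @export
flag_permutation_significant <- function(de, threshold) {
  thr <- if (inherits(threshold, "perm_threshold")) threshold$threshold else threshold
  mutate(de, perm_sig = .data$P.Value < thr)
}
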