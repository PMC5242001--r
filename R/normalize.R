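#' Norm-exp background correction
#'
#' Models each array's observed linear-scale intensity as signal plus noise,
#' `X = S + B` with `S ~ Exponential(alpha)` and `B ~ Normal(mu, sigma^2)`,
#' and replaces each value by the posterior expected signal `E[S | X = x]`.
#' Parameters are estimated per array with the mode-based estimator: `mu` is
#' the kernel-density mode (Silverman bandwidth) of intensities below the
#' array mean, `sigma` the root-mean-square spread of values below `mu`, and
#' `alpha` the reciprocal mean excess above `mu`. The correction is strictly
#' positive and monotone within each array.
#'
#' @param tbl Expression tibble (`probe_id` + sample columns), linear scale,
#'   strictly positive.
#' @return A tibble of the same shape with background-corrected intensities.
#' @export
background_correct <- function(tbl) {
  m <- expr_to_matrix(tbl)
  if (any(m <= 0)) {
    abort("linear-scale intensities must be strictly positive",
          class = "ovitx_input_error")
  }
  out <- m
  for (j in seq_len(ncol(m))) {
    pars <- normexp_fit(m[, j])
    out[, j] <- normexp_signal(m[, j], pars$mu, pars$sigma, pars$alpha)
  }
  matrix_to_expr(out, id_name = names(tbl)[1L])
}

# Mode-based norm-exp parameter estimation for one array.
normexp_fit <- function(x) {
  if (sd(x) == 0) {
    abort("cannot estimate background parameters on a constant array",
          class = "ovitx_estimation_error")
  }
  lower <- x[x < mean(x)]
  d <- density(lower, bw = "nrd0")
  mu <- d$x[which.max(d$y)]
  below <- x[x < mu]
  if (length(below) < 2) below <- lower
  sigma <- sqrt(mean((below - mu)^2))
  above <- x[x > mu]
  alpha <- 1 / mean(above - mu)
  list(mu = mu, sigma = sigma, alpha = alpha)
}

# Posterior mean E[S | X = x] under the normal + exponential convolution.
# S | X = x is Normal(mu_sf, sigma^2) truncated to S > 0 with
# mu_sf = x - mu - sigma^2 * alpha; the Mills-ratio term is evaluated on the
# log scale for stability far into either tail.
normexp_signal <- function(x, mu, sigma, alpha) {
  mu_sf <- x - mu - sigma^2 * alpha
  z <- mu_sf / sigma
  log_phi <- dnorm(z, log = TRUE)
  log_Phi <- pnorm(z, log.p = TRUE)
  e <- mu_sf + sigma * exp(log_phi - log_Phi)
  pmax(e, 1e-10)
}

#' Quantile normalization between arrays
#'
#' Forces every array to the same empirical distribution: each column's
#' sorted values become the mean of the column-sorted values, assigned back
#' in original rank positions. Ties within a column receive the mean of the
#' reference values at their tied ranks. Row labels are untouched. The
#' transform is idempotent.
#'
#' @param tbl Expression tibble with at least two sample columns of equal
#'   length.
#' @return A tibble of the same shape.
#' @export
quantile_normalize <- function(tbl) {
  m <- expr_to_matrix(tbl)
  if (ncol(m) < 2) {
    abort("quantile normalization needs at least two arrays",
          class = "ovitx_input_error")
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  matrix_to_expr(out, id_name = names(tbl)[1L])
}

#' Median-polish summarization of probe sets to gene-level expression
#'
#' Operates on the log2-scale matrix after background correction and
#' quantile normalization. Probes sharing a gene symbol are summarized by
#' Tukey median polish on their probes-by-samples submatrix; the gene's
#' expression in each sample is the fitted overall effect plus that sample's
#' column effect (probe affinities are absorbed by the row effects).
#' Single-probe genes pass through unchanged. Probes with an empty gene
#' symbol are excluded from summarization and returned in the
#' `"unannotated"` attribute.
#'
#' @param tbl Log2-scale expression tibble (`probe_id` + sample columns).
#' @param probes Probe annotation tibble (`probe_id`, `gene_symbol`).
#' @return A tibble, `gene` plus one column per sample, with attribute
#'   `"unannotated"` holding the dropped probe rows.
#' @export
summarize_probesets <- function(tbl, probes) {
  if (is.null(probes) || nrow(probes) == 0) {
    abort("empty probe-to-gene mapping", class = "ovitx_input_error")
  }
  m <- expr_to_matrix(tbl)
  sym <- probes$gene_symbol[match(rownames(m), probes$probe_id)]
  if (anyNA(sym)) {
    abort(sprintf("probe '%s' missing from the annotation",
                  rownames(m)[is.na(sym)][1L]),
          class = "ovitx_consistency_error")
  }
  keep <- !is.na(sym) & sym != ""
  unannotated <- matrix_to_expr(m[!keep, , drop = FALSE], id_name = names(tbl)[1L])
  m <- m[keep, , drop = FALSE]
  sym <- sym[keep]

  genes <- unique(sym)
  out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(m),
                dimnames = list(genes, colnames(m)))
  idx <- split(seq_along(sym), sym)
  for (g in genes) {
    rows <- idx[[g]]
    if (length(rows) == 1L) {
      out[g, ] <- m[rows, ]
    } else {
      mp <- median_polish(m[rows, , drop = FALSE])
      out[g, ] <- mp$overall + mp$col
    }
  }
  res <- matrix_to_expr(out, id_name = "gene")
  attr(res, "unannotated") <- unannotated
  res
}

#' Tukey median polish
#'
#' Alternating removal of row and column medians (rows first, midpoint
#' convention for even-length medians), starting from zero effects, for at
#' most `max_iter` sweeps or until the total absolute residual change falls
#' below `tol`.
#'
#' @param m Numeric matrix.
#' @param max_iter Maximum number of sweeps.
#' @param tol Absolute convergence tolerance on the change in total absolute
#'   residuals.
#' @return List with `overall`, `row`, `col` effects and the residual
#'   matrix `residuals` (`m = overall + row + col + residuals`).
#' @export
median_polish <- function(m, max_iter = 10L, tol = 0.01) {
  r <- m
  re <- rep(0, nrow(m))
  ce <- rep(0, ncol(m))
  overall <- 0
  oldsum <- sum(abs(r))
  for (it in seq_len(max_iter)) {
    rdelta <- apply(r, 1, median)
    r <- r - rdelta
    re <- re + rdelta
    delta <- median(ce)
    ce <- ce - delta
    overall <- overall + delta

    cdelta <- apply(r, 2, median)
    r <- sweep(r, 2, cdelta)
    ce <- ce + cdelta
    delta <- median(re)
    re <- re - delta
    overall <- overall + delta

    newsum <- sum(abs(r))
    if (abs(oldsum - newsum) < tol) break
    oldsum <- newsum
  }
  list(overall = overall, row = re, col = ce, residuals = r)
}

#' RMA-style preprocessing: background, quantile, log2, summarize
#'
#' The full preprocessing chain in the canonical order: norm-exp background
#' correction, between-array quantile normalization, log2 transform (the
#' background step guarantees positivity; no pseudo-count), and
#' median-polish summarization to gene level.
#'
#' @param tbl Linear-scale probe intensity tibble.
#' @param probes Probe annotation tibble.
#' @param skip_background If `TRUE`, omit the background-correction step
#'   (useful for already background-adjusted inputs).
#' @return Gene-level log2 expression tibble, as from
#'   [summarize_probesets()].
#' @export
#' @examples
#' sim <- simulate_experiment(simulation_config(n_genes = 50, seed = 1))
#' expr <- rma(sim$intensities, sim$probes)
rma <- function(tbl, probes, skip_background = FALSE) {
  if (!skip_background) tbl <- background_correct(tbl)
  tbl <- quantile_normalize(tbl)
  m <- expr_to_matrix(tbl)
  tbl <- matrix_to_expr(log2(m), id_name = names(tbl)[1L])
  summarize_probesets(tbl, probes)
}
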