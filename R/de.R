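#' Fit per-gene group-mean linear models
#'
#' One linear model per gene across all groups: group means are arithmetic
#' means of log2 expression and the residual variance is pooled across all
#' groups, `s2_g = RSS_g / (N - k)` with `d_g = N - k` residual degrees of
#' freedom (N samples, k groups). Using all arrays for variance estimation
#' is the standard design for a three-group layout analysed by pairwise
#' treatment-vs-control contrasts.
#'
#' @param expr Gene-level log2 expression tibble (`gene` + sample columns).
#' @param design Design tibble with columns `sample`, `group`; every group
#'   needs at least two samples.
#' @return A `de_fit` object: gene names, group-mean matrix, `s2` (pooled
#'   residual variances), `df_residual`, per-group sizes, and the design.
#' @export
fit_linear_model <- function(expr, design) {
  m <- expr_to_matrix(expr)
  check_design(design, colnames(m))
  grp <- group_of(design, colnames(m))
  sizes <- table(grp)
  if (any(sizes < 2)) {
    abort(sprintf("group '%s' has fewer than 2 samples",
                  names(sizes)[sizes < 2][1L]),
          class = "ovitx_design_error")
  }
  groups <- names(sizes)
  ind <- outer(grp, groups, "==") * 1
  means <- m %*% sweep(ind, 2, colSums(ind), "/")
  colnames(means) <- groups
  fitted <- means[, match(grp, groups), drop = FALSE]
  rss <- rowSums((m - fitted)^2)
  d_g <- ncol(m) - length(groups)
  structure(list(
    genes = rownames(m),
    means = means,
    s2 = rss / d_g,
    df_residual = d_g,
    n_per_group = setNames(as.integer(sizes), groups),
    design = design
  ), class = "de_fit")
}

#' @export
print.de_fit <- function(x, ...) {
  cat(sprintf("<de_fit> %d genes, groups: %s, residual df = %d\n",
              length(x$genes),
              paste(sprintf("%s(%d)", names(x$n_per_group), x$n_per_group),
                    collapse = ", "),
              x$df_residual))
  invisible(x)
}

#' Estimate the empirical-Bayes variance prior
#'
#' Method-of-moments fit of the gene-wise residual variances to a scaled-F
#' model: `s2_g ~ s2_0 * F(d_g, d_0)`. On the log scale the moments are
#' matched through the digamma/trigamma functions; `d_0` solves
#' `trigamma(d_0/2) = var(e) - trigamma(d_g/2)` where
#' `e = log(s2_g) - digamma(d_g/2) + log(d_g/2)`. When the empirical spread
#' of `log(s2_g)` does not exceed the trigamma floor the prior degrees of
#' freedom are infinite (no excess variability beyond sampling noise) and
#' `s2_0` is the common variance. Estimates are floored at 0.01 and treated
#' as infinite above 1e6.
#'
#' @param s2 Vector of gene-wise residual variances.
#' @param d_g Residual degrees of freedom (scalar, shared by all genes).
#' @return List with `d0` (possibly `Inf`) and `s2_0`.
#' @export
estimate_prior <- function(s2, d_g) {
  pos <- s2[s2 > 0 & is.finite(s2)]
  if (length(pos) < 2) {
    abort("need at least two positive residual variances", class = "ovitx_input_error")
  }
  z <- log(pos)
  if (max(z) - min(z) < 1e-12) {
    # exactly equal variances: no sampling spread at all, so the common
    # value itself is the prior
    return(list(d0 = Inf, s2_0 = pos[1L]))
  }
  e <- z - digamma(d_g / 2) + log(d_g / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- var(e)           # n-1 denominator, unbiased under normality of e
  excess <- evar - trigamma(d_g / 2)
  if (!is.finite(excess) || excess <= 0) {
    return(list(d0 = Inf, s2_0 = exp(emean)))
  }
  d0 <- 2 * trigamma_inverse(excess)
  if (d0 > 1e6) {
    return(list(d0 = Inf, s2_0 = exp(emean)))
  }
  d0 <- max(d0, 0.01)
  s2_0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s2_0 = s2_0)
}

# Solve trigamma(y) = x by Newton iteration on 1/y-like scale.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Moderated t-statistics for a treatment-vs-reference contrast
#'
#' Shrinks each gene's residual variance toward the prior,
#' `s2_tilde = (d_0 s2_0 + d_g s2_g) / (d_0 + d_g)`, and tests the contrast
#' `beta = mean(treatment) - mean(reference)` with
#' `t = beta / sqrt(s2_tilde (1/n_t + 1/n_r))` on `d_0 + d_g` degrees of
#' freedom. With `d_0 = Inf` the posterior variance equals `s2_0` and the
#' reference distribution is normal; with `d_0 = 0` the statistic reduces to
#' the ordinary pooled-variance t.
#'
#' @param fit A `de_fit` from [fit_linear_model()].
#' @param prior Prior list from [estimate_prior()] (or a manual
#'   `list(d0 =, s2_0 =)`).
#' @param contrast Character vector `c(treatment, reference)`.
#' @return A tibble: `gene`, `logFC`, `t`, `df`, `P.Value`, `s2`,
#'   `s2_tilde`, with the contrast label in attribute `"contrast"`.
#' @export
moderated_t <- function(fit, prior, contrast) {
  if (length(contrast) != 2 || contrast[1] == contrast[2]) {
    abort("contrast must be c(treatment, reference) with distinct groups",
          class = "ovitx_design_error")
  }
  if (!all(contrast %in% colnames(fit$means))) {
    abort(sprintf("unknown group in contrast: %s",
                  paste(setdiff(contrast, colnames(fit$means)), collapse = ", ")),
          class = "ovitx_design_error")
  }
  d0 <- prior$d0
  s2_0 <- prior$s2_0
  d_g <- fit$df_residual
  s2_tilde <- if (is.infinite(d0)) {
    rep(s2_0, length(fit$s2))
  } else if (d0 == 0) {
    fit$s2
  } else {
    (d0 * s2_0 + d_g * fit$s2) / (d0 + d_g)
  }
  n_t <- fit$n_per_group[[contrast[1]]]
  n_r <- fit$n_per_group[[contrast[2]]]
  beta <- fit$means[, contrast[1]] - fit$means[, contrast[2]]
  se <- sqrt(s2_tilde * (1 / n_t + 1 / n_r))
  t_tilde <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
  df_total <- d0 + d_g
  p <- 2 * pt(-abs(t_tilde), df = df_total)
  p <- pmin(pmax(p, 0), 1)
  out <- tibble(
    gene = fit$genes,
    logFC = unname(beta),
    t = unname(t_tilde),
    df = df_total,
    P.Value = unname(p),
    s2 = unname(fit$s2),
    s2_tilde = unname(s2_tilde)
  )
  attr(out, "contrast") <- paste(contrast, collapse = "_vs_")
  out
}

#' Run the full differential-expression stage
#'
#' Fits the per-gene linear model, estimates the variance prior once from
#' the observed data, computes moderated t-statistics for every requested
#' contrast, and appends Benjamini-Hochberg adjusted p-values per contrast.
#'
#' @param expr Gene- or probe-level log2 expression tibble.
#' @param design Design tibble (`sample`, `group`).
#' @param contrasts List of `c(treatment, reference)` pairs; defaults to
#'   every non-control group versus `control`.
#' @return A `de_result` object: a tibble with columns `contrast`, `gene`,
#'   `logFC`, `t`, `df`, `P.Value`, `adj.P.Val` (plus shrinkage columns),
#'   carrying the fit and prior in attributes `"fit"` and `"prior"`.
#' @export
#' @examples
#' sim <- simulate_experiment(simulation_config(n_genes = 120, seed = 1))
#' expr <- rma(sim$intensities, sim$probes)
#' de <- run_de(expr, sim$design)
#' glance(de)
run_de <- function(expr, design, contrasts = NULL) {
  fit <- fit_linear_model(expr, design)
  if (is.null(contrasts)) {
    contrasts <- lapply(setdiff(colnames(fit$means), "control"),
                        function(g) c(g, "control"))
  }
  prior <- estimate_prior(fit$s2, fit$df_residual)
  tabs <- lapply(contrasts, function(ctr) {
    tab <- moderated_t(fit, prior, ctr)
    mutate(tab,
           contrast = attr(tab, "contrast"),
           adj.P.Val = bh_adjust(.data$P.Value),
           .before = 1L)
  })
  out <- bind_rows(tabs)
  out <- select(out, "contrast", "gene", "logFC", "t", "df", "P.Value",
                "adj.P.Val", "s2", "s2_tilde")
  attr(out, "fit") <- fit
  attr(out, "prior") <- prior
  class(out) <- c("de_result", class(out))
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a differential-expression result
#'
#' @param x A `de_result` from [run_de()].
#' @param ... Unused.
#' @return A plain tibble of per-gene, per-contrast statistics.
#' @export
tidy.de_result <- function(x, ...) {
  out <- x
  attr(out, "fit") <- NULL
  attr(out, "prior") <- NULL
  class(out) <- class(tibble())
  out
}

#' One-row summary of a differential-expression result
#'
#' @param x A `de_result` from [run_de()].
#' @param ... Unused.
#' @return A tibble with the prior degrees of freedom and variance, gene and
#'   sample counts, and residual degrees of freedom.
#' @export
glance.de_result <- function(x, ...) {
  fit <- attr(x, "fit")
  prior <- attr(x, "prior")
  tibble(
    n_genes = length(fit$genes),
    n_samples = sum(fit$n_per_group),
    df_residual = fit$df_residual,
    d0 = prior$d0,
    s2_0 = prior$s2_0,
    n_contrasts = length(unique(x$contrast))
  )
}
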