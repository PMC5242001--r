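# Shared fixture builders; everything is generated in code.

make_expr <- function(m, id_name = "gene") {
  tibble::as_tibble(m) |>
    (\(d) dplyr::bind_cols(tibble::tibble(!!id_name := rownames(m)), d))()
}

# A 3-group, 4-arrays-per-group design.
study_design <- function(groups = c("control", "mating", "sf"), n_per = 4L) {
  tibble::tibble(
    sample = unlist(lapply(groups, function(g) paste(g, seq_len(n_per), sep = "_"))),
    group = rep(groups, each = n_per)
  )
}

# Gene-level log2 expression with gene variances drawn from a scaled
# inverse-chi-square family; optional planted effects for one treatment.
null_expr_matrix <- function(n_genes, design, s2_0 = 0.0625, d0 = 4,
                             baseline = 8, seed = 1) {
  withr::with_seed(seed, {
    vars <- s2_0 * d0 / stats::rchisq(n_genes, d0)
    m <- baseline + sweep(matrix(stats::rnorm(n_genes * nrow(design)), n_genes),
                          1, sqrt(vars), "*")
    dimnames(m) <- list(sprintf("g%05d", seq_len(n_genes)), design$sample)
    m
  })
}

# Brute-force step-up BH, written straight from the definition.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Quadrature oracle for the norm-exp posterior mean E[S | X = x]. The
# posterior is a truncated normal centred near x - mu, so integrating over a
# wide finite window around it keeps the quadrature stable far from zero.
normexp_oracle <- function(x, mu, sigma, alpha) {
  f <- function(s) stats::dexp(s, alpha) * stats::dnorm(x - s, mu, sigma)
  lo <- max(0, x - mu - 15 * sigma)
  hi <- max(x - mu + 15 * sigma, 20 * sigma)
  num <- stats::integrate(function(s) s * f(s), lo, hi, rel.tol = 1e-12)$value
  den <- stats::integrate(f, lo, hi, rel.tol = 1e-12)$value
  num / den
}

# Factorial-sum binomial tail, the slow-but-obvious oracle.
binom_tail_brute <- function(obs, n, p, side) {
  ks <- if (side == "over") obs:n else 0:obs
  sum(vapply(ks, function(k) choose(n, k) * p^k * (1 - p)^(n - k), numeric(1)))
}
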