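test_that("norm-exp posterior mean matches a quadrature oracle at fixed parameters", {
  mu <- 100; sigma <- 15; alpha <- 1 / 500
  for (x in c(60, 90, 100, 120, 200, 1000, 3000)) {
    expect_equal(ovitx:::normexp_signal(x, mu, sigma, alpha),
                 normexp_oracle(x, mu, sigma, alpha),
                 tolerance = 1e-6)
  }
  # far above the noise band the correction approaches x - mu
  x <- mu + 10 * sigma + 2000
  expect_equal(ovitx:::normexp_signal(x, mu, sigma, alpha), x - mu,
               tolerance = 0.01)
})

test_that("background correction is positive and monotone within each array", {
  set.seed(21)
  m <- matrix(rexp(500, 1 / 300) + rnorm(500, 80, 10), ncol = 5,
              dimnames = list(sprintf("p%03d", 1:100), sprintf("s%d", 1:5)))
  m <- pmax(m, 1)
  out <- expr_to_mat <- as.matrix(background_correct(make_expr(m, "probe_id"))[, -1])
  expect_true(all(out > 0))
  for (j in 1:5) {
    expect_true(all(diff(out[order(m[, j]), j]) >= 0))
  }
  const <- make_expr(matrix(5, 10, 2, dimnames = list(letters[1:10], c("a", "b"))),
                     "probe_id")
  expect_error(background_correct(const), class = "ovitx_estimation_error")
})

test_that("quantile normalization matches the mean-of-order-statistics definition", {
  m <- matrix(c(1, 2, 3, 4), ncol = 2,
              dimnames = list(c("p1", "p2"), c("s1", "s2")))
  out <- as.matrix(quantile_normalize(make_expr(m, "probe_id"))[, -1])
  expect_equal(unname(out), matrix(c(2, 3, 2, 3), ncol = 2))

  set.seed(5)
  m <- matrix(rnorm(600), ncol = 6,
              dimnames = list(sprintf("p%03d", 1:100), sprintf("s%d", 1:6)))
  tbl <- make_expr(m, "probe_id")
  out <- as.matrix(quantile_normalize(tbl)[, -1])
  ref <- rowMeans(apply(m, 2, sort))
  for (j in 1:6) {
    expect_equal(sort(out[, j]), ref, ignore_attr = TRUE)
    expect_equal(unname(rank(out[, j])), unname(rank(m[, j])))
  }
  expect_equal(apply(out, 2, mean), setNames(rep(mean(ref), 6), colnames(m)))
})

test_that("quantile normalization is idempotent and keeps identical columns fixed", {
  same <- matrix(rep(c(3, 1, 2), 4), ncol = 4,
                 dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:4)))
  tbl <- make_expr(same, "probe_id")
  expect_equal(quantile_normalize(tbl), tbl)

  set.seed(6)
  m <- matrix(rnorm(200), ncol = 4,
              dimnames = list(sprintf("p%02d", 1:50), sprintf("s%d", 1:4)))
  once <- quantile_normalize(make_expr(m, "probe_id"))
  twice <- quantile_normalize(once)
  expect_equal(twice, once)
})

test_that("tied values receive the mean of reference values at their tied ranks", {
  m <- matrix(c(1, 1, 5, 2, 4, 6), ncol = 2,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  out <- as.matrix(quantile_normalize(make_expr(m, "probe_id"))[, -1])
  ref <- unname(rowMeans(cbind(sort(m[, 1]), sort(m[, 2]))))  # (1.5, 2.5, 5.5)
  expect_equal(unname(out[, 2]), ref)
  expect_equal(unname(out[1:2, 1]), rep(mean(ref[1:2]), 2))
  expect_equal(unname(out[3, 1]), ref[3])
})

test_that("median polish recovers exactly additive structure", {
  row_eff <- c(0.5, -1, 2, 0)
  col_eff <- c(1, -2, 0.5, 0, 3)
  m <- outer(row_eff, col_eff, "+") + 7
  mp <- median_polish(m)
  expect_equal(max(abs(mp$residuals)), 0, tolerance = 1e-12)
  fitted_col <- mp$overall + mp$col
  expect_equal(diff(fitted_col), diff(col_eff + 7), tolerance = 1e-12)

  # at convergence, row and column medians of residuals vanish
  set.seed(8)
  r <- matrix(rnorm(35), 5, 7)
  mp2 <- median_polish(r, max_iter = 100L, tol = 1e-9)
  expect_lt(max(abs(apply(mp2$residuals, 1, median))), 1e-6)
  expect_lt(max(abs(apply(mp2$residuals, 2, median))), 1e-6)
})

test_that("probe-set summarization handles constants, singletons and unannotated probes", {
  design_samples <- c("s1", "s2", "s3")
  m <- rbind(
    pA_1 = c(3, 3, 3), pA_2 = c(3, 3, 3),       # constant gene
    pB_1 = c(1, 2, 3),                          # single-probe gene
    pU_1 = c(9, 9, 9)                           # uncharacterized
  )
  colnames(m) <- design_samples
  probes <- tibble::tibble(
    probe_id = rownames(m),
    gene_symbol = c("A", "A", "B", ""),
    characterized = c(TRUE, TRUE, TRUE, FALSE))
  out <- summarize_probesets(make_expr(m, "probe_id"), probes)
  expect_setequal(out$gene, c("A", "B"))
  expect_equal(unlist(out[out$gene == "A", -1]), c(s1 = 3, s2 = 3, s3 = 3))
  expect_equal(unlist(out[out$gene == "B", -1]), c(s1 = 1, s2 = 2, s3 = 3))
  dropped <- attr(out, "unannotated")
  expect_equal(dropped$probe_id, "pU_1")

  expect_error(summarize_probesets(make_expr(m, "probe_id"), probes[1:3, ]),
               class = "ovitx_consistency_error")
  expect_error(summarize_probesets(make_expr(m, "probe_id"), probes[0, ]),
               class = "ovitx_input_error")
})

test_that("multi-probe summarization recovers additive probe effects up to offset", {
  samples <- sprintf("s%d", 1:6)
  col_eff <- c(0, 1, -0.5, 2, 0.25, -1)
  probe_eff <- c(-0.3, 0, 0.8)
  m <- outer(probe_eff, col_eff, "+") + 10
  dimnames(m) <- list(c("p1", "p2", "p3"), samples)
  probes <- tibble::tibble(probe_id = rownames(m), gene_symbol = "G",
                           characterized = TRUE)
  out <- summarize_probesets(make_expr(m, "probe_id"), probes)
  vals <- unlist(out[1, -1])
  expect_equal(unname(diff(vals)), diff(col_eff), tolerance = 1e-9)
})

test_that("the full RMA chain produces one gene-level log2 row per symbol", {
  sim <- simulate_experiment(simulation_config(n_genes = 40, seed = 13))
  expr <- rma(sim$intensities, sim$probes)
  expect_equal(sort(expr$gene),
               sort(unique(sim$probes$gene_symbol[sim$probes$characterized])))
  expect_equal(names(expr)[-1], sim$design$sample)
  expect_equal(nrow(attr(expr, "unannotated")),
               sum(!sim$probes$characterized))
})
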