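test_that("group means and pooled residual variance match direct arithmetic", {
  design <- study_design()
  vals <- c(1, 2, 3, 4,   5, 6, 7, 8,   2, 2, 4, 4)
  m <- matrix(vals, nrow = 1, dimnames = list("g1", design$sample))
  fit <- fit_linear_model(make_expr(m), design)
  expect_equal(fit$means["g1", ], c(control = 2.5, mating = 6.5, sf = 3))
  rss <- sum((vals[1:4] - 2.5)^2) + sum((vals[5:8] - 6.5)^2) + sum((vals[9:12] - 3)^2)
  expect_equal(fit$s2[["g1"]], rss / 9)
  expect_equal(fit$df_residual, 9L)

  flat <- matrix(7, 1, 12, dimnames = list("g2", design$sample))
  fit2 <- fit_linear_model(make_expr(flat), design)
  expect_true(all(fit2$means == 7))
  expect_equal(unname(fit2$s2), 0)

  small <- design[design$sample != "sf_4" & design$sample != "sf_3" &
                    design$sample != "sf_2", ]
  expect_error(
    fit_linear_model(make_expr(m[, small$sample, drop = FALSE]), small),
    class = "ovitx_design_error")
})

test_that("the variance prior is recovered from scaled inverse-chi-square draws", {
  d0_true <- 4; s2_0_true <- 0.05; d_g <- 9
  withr::with_seed(101, {
    s2 <- s2_0_true * rchisq(20000, d_g) / d_g *
      (d0_true / rchisq(20000, d0_true))
  })
  prior <- estimate_prior(s2, d_g)
  expect_lt(abs(prior$d0 - d0_true) / d0_true, 0.15)
  expect_lt(abs(prior$s2_0 - s2_0_true) / s2_0_true, 0.10)
})

test_that("identical variances yield an infinite prior at the common value", {
  prior <- estimate_prior(rep(0.05, 500), 9)
  expect_identical(prior$d0, Inf)
  expect_equal(prior$s2_0, 0.05)
})

test_that("the prior df is scale-invariant and the prior variance scale-equivariant", {
  withr::with_seed(7, s2 <- 0.1 * 4 / rchisq(5000, 4) * rchisq(5000, 9) / 9)
  a <- estimate_prior(s2, 9)
  b <- estimate_prior(s2 * 3.7, 9)
  expect_equal(a$d0, b$d0, tolerance = 1e-8)
  expect_equal(b$s2_0 / a$s2_0, 3.7, tolerance = 1e-8)
})

test_that("moderated t handles the degenerate and limiting priors", {
  design <- study_design()
  withr::with_seed(3, {
    m <- matrix(rnorm(20 * 12, 8, 0.5), 20,
                dimnames = list(sprintf("g%02d", 1:20), design$sample))
  })
  # a gene with exactly equal group means
  m[1, ] <- rep(c(1, 2, 3, 4), 3)
  fit <- fit_linear_model(make_expr(m), design)

  prior <- estimate_prior(fit$s2, fit$df_residual)
  mt <- moderated_t(fit, prior, c("mating", "control"))
  expect_equal(mt$t[1], 0)
  expect_equal(mt$P.Value[1], 1)

  # d0 = 0 reduces to the ordinary pooled-variance t on d_g df
  mt0 <- moderated_t(fit, list(d0 = 0, s2_0 = 1), c("mating", "control"))
  beta <- fit$means[, "mating"] - fit$means[, "control"]
  t_ord <- beta / sqrt(fit$s2 * (1 / 4 + 1 / 4))
  expect_equal(mt0$t, unname(t_ord))
  expect_equal(mt0$P.Value, unname(2 * pt(-abs(t_ord), 9)))

  # d0 = Inf pins every posterior variance at s2_0
  mtInf <- moderated_t(fit, list(d0 = Inf, s2_0 = 0.33), c("mating", "control"))
  expect_true(all(mtInf$s2_tilde == 0.33))
})

test_that("shrinkage moves variances toward the prior and p is monotone in |t|", {
  design <- study_design()
  m <- null_expr_matrix(500, design, seed = 19)
  fit <- fit_linear_model(make_expr(m), design)
  prior <- estimate_prior(fit$s2, fit$df_residual)
  mt <- moderated_t(fit, prior, c("sf", "control"))
  below <- mt$s2 < prior$s2_0
  expect_true(all(mt$s2_tilde[below] > mt$s2[below]))
  expect_true(all(mt$s2_tilde[!below & mt$s2 > prior$s2_0] <
                    mt$s2[!below & mt$s2 > prior$s2_0]))
  expect_true(all(mt$s2_tilde >= pmin(mt$s2, prior$s2_0) - 1e-12))
  expect_true(all(mt$s2_tilde <= pmax(mt$s2, prior$s2_0) + 1e-12))

  ord <- order(abs(mt$t))
  expect_true(all(diff(mt$P.Value[ord]) <= 1e-12))
})

test_that("moderation agrees with the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  design <- study_design()
  m <- null_expr_matrix(2000, design, seed = 23)
  fit <- fit_linear_model(make_expr(m), design)
  prior <- estimate_prior(fit$s2, fit$df_residual)
  mt <- moderated_t(fit, prior, c("mating", "control"))

  X <- stats::model.matrix(~0 + design$group)
  colnames(X) <- levels(factor(design$group))
  lf <- limma::lmFit(m, X)
  cf <- limma::contrasts.fit(lf, limma::makeContrasts(mating - control, levels = X))
  eb <- limma::eBayes(cf)
  expect_equal(prior$d0, unname(eb$df.prior), tolerance = 1e-6)
  expect_equal(prior$s2_0, unname(eb$s2.prior), tolerance = 1e-6)
  expect_equal(mt$t, unname(eb$t[, 1]), tolerance = 1e-8)
  expect_equal(mt$P.Value, unname(eb$p.value[, 1]), tolerance = 1e-8)
})

test_that("type-I error under the global null is nominal", {
  design <- study_design()
  rates <- vapply(1:20, function(s) {
    m <- null_expr_matrix(2000, design, seed = 1000 + s)
    de <- run_de(make_expr(m), design, contrasts = list(c("mating", "control")))
    mean(de$P.Value < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.01)
})

test_that("run_de reports both default contrasts with BH adjustment and a glance summary", {
  design <- study_design()
  m <- null_expr_matrix(300, design, seed = 31)
  de <- run_de(make_expr(m), design)
  expect_setequal(unique(de$contrast), c("mating_vs_control", "sf_vs_control"))
  one <- de[de$contrast == "mating_vs_control", ]
  expect_equal(one$adj.P.Val, bh_adjust(one$P.Value))
  g <- glance(de)
  expect_equal(g$n_genes, 300L)
  expect_equal(g$df_residual, 9L)
  expect_s3_class(tidy(de), "tbl_df")
})
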