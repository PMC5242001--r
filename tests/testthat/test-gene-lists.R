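probes_fixture <- function(ids, symbols) {
  tibble::tibble(probe_id = ids, gene_symbol = symbols,
                 characterized = symbols != "")
}

test_that("redundant probes collapse to the minimum-p representative", {
  de <- tibble::tibble(probe_id = c("P1", "P2", "P3"),
                       logFC = c(1.2, -0.8, 2.0),
                       P.Value = c(0.01, 0.03, 0.2))
  probes <- probes_fixture(c("P1", "P2", "P3"), c("A", "A", "B"))
  out <- collapse_probes(de, probes)
  expect_equal(out$gene, "A")
  expect_equal(out$probe_id, "P1")
  expect_equal(out$P.Value, 0.01)
  expect_equal(out$direction, "up")

  # tie on p: larger |logFC| wins, then lexicographic probe id
  de2 <- tibble::tibble(probe_id = c("P1", "P2", "P3"),
                        logFC = c(1, -3, 3),
                        P.Value = c(0.02, 0.02, 0.02))
  out2 <- collapse_probes(de2, probes_fixture(c("P1", "P2", "P3"), rep("A", 3)))
  expect_equal(out2$probe_id, "P2")
  expect_equal(out2$direction, "down")
})

test_that("uncharacterized and non-significant probes never reach the list", {
  de <- tibble::tibble(probe_id = c("P1", "P2"), logFC = c(2, -2),
                       P.Value = c(0.001, 0.001))
  all_unchar <- probes_fixture(c("P1", "P2"), c("", ""))
  expect_equal(nrow(collapse_probes(de, all_unchar)), 0)

  named <- probes_fixture(c("P1", "P2"), c("A", "B"))
  weak <- dplyr::mutate(de, P.Value = c(0.06, 0.2))
  expect_equal(nrow(collapse_probes(weak, named)), 0)

  # unique symbols, all significant: identity case
  out <- collapse_probes(de, named)
  expect_equal(nrow(out), 2)
  expect_setequal(out$gene, c("A", "B"))

  zero <- tibble::tibble(probe_id = "P1", logFC = 0, P.Value = 0.001)
  expect_equal(nrow(collapse_probes(zero, named[1, ])), 0)

  expect_error(collapse_probes(de, named[1, ]), class = "ovitx_consistency_error")
})

test_that("volcano classification follows the p and fold-change rules", {
  de <- tibble::tibble(
    probe_id = sprintf("P%d", 1:4),
    logFC = c(1.5, 0.5, -2, 0.2),
    P.Value = c(0.01, 0.01, 0.001, 0.5),
    adj.P.Val = c(0.2, 0.2, 0.01, 0.9))
  cls <- classify_volcano(de)$volcano_class
  expect_equal(as.character(cls),
               c("significant_high_fc", "significant",
                 "fdr_significant_high_fc", "ns"))
})

test_that("direction-aware overlap partitions the union of the two lists", {
  gl <- function(genes, dirs) tibble::tibble(gene = genes, direction = dirs)
  a <- gl(c("x", "y"), c("up", "down"))
  b <- gl(c("x", "y"), c("up", "up"))
  ov <- venn_overlap(a, b)
  expect_equal(ov$common_up, "x")
  expect_equal(ov$discordant, "y")
  expect_equal(length(ov$common_down), 0)

  disjoint <- venn_overlap(gl(c("a", "b"), c("up", "down")),
                           gl(c("c", "d"), c("up", "down")))
  expect_equal(length(disjoint$common_up) + length(disjoint$common_down), 0)
  expect_equal(unname(disjoint$counts$n[disjoint$counts$section == "a_only_up"]), 1L)

  same <- venn_overlap(a, a)
  expect_equal(same$common_up, "x")
  expect_equal(same$common_down, "y")
  expect_equal(sum(same$counts$n[grepl("only", same$counts$section)]), 0L)

  # partition: sections are disjoint and cover the union
  withr::with_seed(10, {
    g1 <- sample(letters, 15)
    g2 <- sample(letters, 15)
    A <- gl(g1, sample(c("up", "down"), 15, TRUE))
    B <- gl(g2, sample(c("up", "down"), 15, TRUE))
  })
  ov2 <- venn_overlap(A, B)
  parts <- ov2[setdiff(names(ov2), "counts")]
  all_genes <- unlist(parts)
  expect_equal(anyDuplicated(all_genes), 0L)
  expect_setequal(all_genes, union(A$gene, B$gene))
})

test_that("top-N selection ranks by signed fold change with deterministic ties", {
  withr::with_seed(12, {
    up <- tibble::tibble(gene = sprintf("U%03d", 1:150),
                         logFC = runif(150, 0.1, 5),
                         P.Value = runif(150, 0, 0.05),
                         direction = "up")
  })
  top <- top_n_by_lfc(up, n_up = 100, n_down = 100)
  expect_equal(nrow(top), 100)
  expect_gte(min(top$logFC), sort(up$logFC, decreasing = TRUE)[100])

  small <- dplyr::bind_rows(
    head(up, 40),
    tibble::tibble(gene = sprintf("D%02d", 1:20), logFC = -runif(20),
                   P.Value = 0.01, direction = "down"))
  expect_equal(nrow(top_n_by_lfc(small)), 60)

  tied <- tibble::tibble(gene = c("A", "B", "C"),
                         logFC = c(2, 1, 1),
                         P.Value = c(0.01, 0.004, 0.002),
                         direction = "up")
  picked <- top_n_by_lfc(tied, n_up = 2, n_down = 0)
  expect_equal(picked$gene, c("A", "C"))
})

test_that("stronger planted effects put more planted genes into the top list", {
  # magnitudes kept within quantile normalization's validity domain (a
  # mostly-unchanged transcriptome); very large planted shifts on a large
  # gene fraction distort the common target distribution itself
  frac_planted <- vapply(c(0.5, 1, 2), function(mag) {
    hits <- vapply(1:3, function(s) {
      sim <- simulate_experiment(simulation_config(
        n_genes = 400, probes_per_gene = c(1L, 2L), frac_de_per_contrast = 0.1,
        lfc_magnitude = mag, seed = 600 + s))
      expr <- rma(sim$intensities, sim$probes)
      de <- run_de(expr, sim$design, contrasts = list(c("mating", "control")))
      de$probe_id <- de$gene  # gene-level rows collapse as themselves
      lst <- collapse_probes(de, tibble::tibble(probe_id = de$gene,
                                                gene_symbol = de$gene,
                                                characterized = TRUE))
      top <- top_n_by_lfc(lst, 25, 25)
      planted <- sim$truth$de$gene[sim$truth$de$contrast == "mating_vs_control"]
      mean(top$gene %in% planted)
    }, numeric(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(frac_planted) >= 0))
})
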