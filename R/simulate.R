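#' Configuration for a synthetic sperm-reservoir microarray experiment
#'
#' Describes a seeded probe-level experiment emulating the study design this
#' package targets: three groups of four arrays (unmated control, natural
#' mating, sperm-free seminal-fluid infusion), redundant probes per gene,
#' a fraction of uncharacterized probes, gene-wise variance heterogeneity
#' drawn from a scaled inverse-chi-square family (so empirical-Bayes
#' shrinkage is exercised with a recoverable prior), and per-array
#' multiplicative distortion (so quantile normalization has work to do).
#'
#' @param n_genes Number of characterized genes on the array.
#' @param probes_per_gene Integer vector `c(min, max)`; each gene receives a
#'   uniformly drawn number of replicate probes in this range.
#' @param frac_uncharacterized Fraction of all probes carrying no gene symbol.
#' @param group_sizes Named integer vector of arrays per group; the default
#'   mirrors the study design (4 control, 4 mating, 4 seminal-fluid).
#' @param frac_de_per_contrast Fraction of genes with a planted effect in
#'   each treatment-vs-control contrast.
#' @param lfc_magnitude Mean absolute planted log2 fold change; individual
#'   magnitudes are drawn uniformly in `[0.5, 1.5] * lfc_magnitude` with
#'   random sign.
#' @param baseline_mean,baseline_sd Mean and SD of gene baseline expression,
#'   log2 scale.
#' @param noise_sd Typical residual standard deviation (log2 units); its
#'   square is the scale of the inverse-chi-square variance distribution.
#' @param noise_sd_shape Degrees of freedom of the scaled inverse-chi-square
#'   variance distribution; smaller values give more gene-to-gene variance
#'   heterogeneity.
#' @param array_scale_jitter SD (log2 units) of the per-array multiplicative
#'   distortion applied after planted effects.
#' @param n_go_terms Number of GO-like categories in the simulated annotation.
#' @param go_term_size_range Integer vector `c(min, max)` of category sizes.
#' @param seed Integer seed; the same seed reproduces the experiment exactly.
#'
#' @return A `simulation_config` object (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(n_genes = 200, seed = 1)
#' sim <- simulate_experiment(cfg)
#' dplyr::glimpse(sim$design)
simulation_config <- function(n_genes = 5000,
                              probes_per_gene = c(1L, 3L),
                              frac_uncharacterized = 0.1,
                              group_sizes = c(control = 4L, mating = 4L, sf = 4L),
                              frac_de_per_contrast = 0.05,
                              lfc_magnitude = 2,
                              baseline_mean = 8,
                              baseline_sd = 1.5,
                              noise_sd = 0.25,
                              noise_sd_shape = 4,
                              array_scale_jitter = 0.1,
                              n_go_terms = 50,
                              go_term_size_range = c(5L, 200L),
                              seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    probes_per_gene = as.integer(probes_per_gene),
    frac_uncharacterized = frac_uncharacterized,
    group_sizes = group_sizes,
    frac_de_per_contrast = frac_de_per_contrast,
    lfc_magnitude = lfc_magnitude,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    noise_sd = noise_sd,
    noise_sd_shape = noise_sd_shape,
    array_scale_jitter = array_scale_jitter,
    n_go_terms = as.integer(n_go_terms),
    go_term_size_range = as.integer(go_term_size_range),
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(msg, class = "ovitx_config_error")
  chk(cfg$n_genes >= 1, "n_genes must be >= 1")
  chk(length(cfg$probes_per_gene) == 2 && all(cfg$probes_per_gene >= 1) &&
        cfg$probes_per_gene[1] <= cfg$probes_per_gene[2],
      "probes_per_gene must be c(min, max) with 1 <= min <= max")
  for (f in c("frac_uncharacterized", "frac_de_per_contrast")) {
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, sprintf("%s must lie in [0, 1]", f))
  }
  chk(!is.null(names(cfg$group_sizes)) && all(cfg$group_sizes >= 1),
      "group_sizes must be a named vector of counts >= 1")
  chk("control" %in% names(cfg$group_sizes), "group_sizes must include 'control'")
  chk(cfg$lfc_magnitude > 0, "lfc_magnitude must be positive")
  chk(cfg$baseline_sd > 0, "baseline_sd must be positive")
  chk(cfg$noise_sd >= 0, "noise_sd must be non-negative")
  chk(cfg$noise_sd_shape > 0, "noise_sd_shape must be positive")
  chk(cfg$array_scale_jitter >= 0, "array_scale_jitter must be non-negative")
  chk(cfg$n_go_terms >= 0, "n_go_terms must be >= 0")
  chk(length(cfg$go_term_size_range) == 2 && all(cfg$go_term_size_range >= 1),
      "go_term_size_range must be c(min, max) with min >= 1")
  invisible(cfg)
}

#' Simulate a probe-level microarray experiment with known ground truth
#'
#' Generates linear-scale intensities for a three-group design with planted
#' log2 fold changes. Planted effects are applied additively on the log2
#' scale to the treatment groups; redundant probes are replicate
#' measurements of their gene's (noisy) expression plus independent probe
#' noise and a fixed probe affinity offset; per-array multiplicative
#' distortion is applied last. Uncharacterized probes carry no gene symbol
#' and no planted effect.
#'
#' @param config A [simulation_config()].
#'
#' @return A `sim_experiment` list with elements
#'   \describe{
#'     \item{intensities}{tibble, `probe_id` plus one linear-scale column per
#'       array (strictly positive).}
#'     \item{design}{tibble with columns `sample`, `group`.}
#'     \item{probes}{tibble with columns `probe_id`, `gene_symbol`
#'       (empty string when uncharacterized), `characterized`.}
#'     \item{go}{tibble with columns `gene`, `term`, `term_name`.}
#'     \item{truth}{list: `de` (tibble `contrast`, `gene`, `lfc`),
#'       `null_genes` (list of character vectors per contrast),
#'       `gene_variances` (tibble `gene`, `variance`).}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort("config must be created by simulation_config()", class = "ovitx_config_error")
  }
  withr::local_seed(config$seed)

  groups <- names(config$group_sizes)
  treatments <- setdiff(groups, "control")
  samples <- unlist(lapply(groups, function(g) {
    paste(g, seq_len(config$group_sizes[[g]]), sep = "_")
  }))
  design <- tibble(
    sample = samples,
    group = rep(groups, times = config$group_sizes)
  )
  n_samp <- nrow(design)
  ng <- config$n_genes
  genes <- sprintf("G%05d", seq_len(ng))

  baseline <- rnorm(ng, config$baseline_mean, config$baseline_sd)
  # scaled inverse-chi-square gene variances: s2 = df * scale / chisq_df
  gene_var <- config$noise_sd^2 * config$noise_sd_shape /
    rchisq(ng, df = config$noise_sd_shape)

  # planted effects, one draw per treatment contrast
  n_de <- round(config$frac_de_per_contrast * ng)
  effect <- matrix(0, nrow = ng, ncol = length(groups),
                   dimnames = list(genes, groups))
  de_rows <- list()
  null_genes <- list()
  for (tg in treatments) {
    contrast <- paste0(tg, "_vs_control")
    if (n_de > 0) {
      idx <- sample.int(ng, n_de)
      lfc <- sample(c(-1, 1), n_de, replace = TRUE) *
        runif(n_de, 0.5, 1.5) * config$lfc_magnitude
      effect[idx, tg] <- lfc
      de_rows[[contrast]] <- tibble(contrast = contrast,
                                    gene = genes[idx], lfc = lfc)
      null_genes[[contrast]] <- genes[-idx]
    } else {
      de_rows[[contrast]] <- tibble(contrast = character(), gene = character(),
                                    lfc = numeric())
      null_genes[[contrast]] <- genes
    }
  }

  # gene x sample log2 signal: baseline + effect + gene-level residual
  grp_idx <- match(design$group, groups)
  mu <- baseline + effect[, grp_idx, drop = FALSE]
  resid <- matrix(rnorm(ng * n_samp, 0, sqrt(gene_var)), nrow = ng)
  signal <- mu + resid
  dimnames(signal) <- list(genes, design$sample)

  # replicate probes: affinity offset (fixed 0.25 log2 SD) + probe noise
  n_probes_per_gene <- if (config$probes_per_gene[1] == config$probes_per_gene[2]) {
    rep(config$probes_per_gene[1], ng)
  } else {
    sample(seq(config$probes_per_gene[1], config$probes_per_gene[2]), ng,
           replace = TRUE)
  }
  gene_of_probe <- rep(seq_len(ng), times = n_probes_per_gene)
  n_char <- length(gene_of_probe)
  affinity <- rnorm(n_char, 0, 0.25)
  probe_noise_sd <- config$noise_sd / 2
  y <- signal[gene_of_probe, , drop = FALSE] + affinity +
    matrix(rnorm(n_char * n_samp, 0, probe_noise_sd), nrow = n_char)

  probe_ids <- sprintf("P%06d", seq_len(n_char))
  probe_tbl <- tibble(probe_id = probe_ids,
                      gene_symbol = genes[gene_of_probe],
                      characterized = TRUE)

  # uncharacterized probes: own baselines, no planted effects
  fu <- config$frac_uncharacterized
  n_unchar <- if (fu > 0 && fu < 1) round(fu / (1 - fu) * n_char) else 0L
  if (n_unchar > 0) {
    ub <- rnorm(n_unchar, config$baseline_mean, config$baseline_sd)
    yu <- ub + matrix(rnorm(n_unchar * n_samp, 0, config$noise_sd), nrow = n_unchar)
    y <- rbind(y, yu)
    probe_tbl <- bind_rows(probe_tbl,
                           tibble(probe_id = sprintf("U%06d", seq_len(n_unchar)),
                                  gene_symbol = "",
                                  characterized = FALSE))
  }
  rownames(y) <- probe_tbl$probe_id
  colnames(y) <- design$sample

  # per-array multiplicative distortion, applied after effects
  if (config$array_scale_jitter > 0) {
    jitter <- rnorm(n_samp, 0, config$array_scale_jitter)
    y <- sweep(y, 2, jitter, "+")
  }

  intensities <- matrix_to_expr(2^y)

  go <- simulate_go_annotation(genes, config$n_go_terms, config$go_term_size_range)

  structure(list(
    intensities = intensities,
    design = design,
    probes = probe_tbl,
    go = go,
    truth = list(
      de = bind_rows(de_rows),
      null_genes = null_genes,
      gene_variances = tibble(gene = genes, variance = gene_var)
    ),
    config = config
  ), class = "sim_experiment")
}

simulate_go_annotation <- function(genes, n_terms, size_range) {
  if (n_terms == 0) {
    return(tibble(gene = character(), term = character(), term_name = character()))
  }
  sizes <- pmin(sample(seq(size_range[1], size_range[2]), n_terms, replace = TRUE),
                length(genes))
  purrr::map2_dfr(seq_len(n_terms), sizes, function(i, k) {
    tibble(gene = sample(genes, k),
           term = sprintf("GO:%07d", i),
           term_name = sprintf("simulated process %d", i))
  })
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("<sim_experiment> %d probes x %d arrays (%d genes, seed %d)\n",
              nrow(x$intensities), nrow(x$design), x$config$n_genes,
              x$config$seed))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s(%d)", names(x$config$group_sizes),
                            x$config$group_sizes), collapse = ", ")))
  cat(sprintf("  planted effects: %d per contrast\n",
              round(x$config$frac_de_per_contrast * x$config$n_genes)))
  invisible(x)
}

#' Build a gene/GO annotation universe with prescribed category sizes
#'
#' Creates a reference universe of exactly `n_ref` gene symbols in which each
#' requested category annotates exactly its requested number of genes (its
#' REF count). Overlap between categories is permitted and seed-controlled.
#' This reproduces the combinatorial setting of an overrepresentation test
#' against a fixed genome-wide reference list.
#'
#' @param n_ref Total number of genes in the reference universe.
#' @param category_specs A data frame with columns `term` and `ref` (REF
#'   count per term), optionally `term_name`; or `NULL` for no categories.
#' @param seed Integer seed controlling category membership.
#'
#' @return A [go_universe] object.
#' @export
#' @examples
#' u <- generate_annotation_universe(
#'   1000, data.frame(term = "GO:0000001", ref = 30), seed = 1)
#' term_ref_counts(u)
generate_annotation_universe <- function(n_ref, category_specs = NULL, seed = 1L) {
  n_ref <- as.integer(n_ref)
  if (n_ref < 1) abort("n_ref must be >= 1", class = "ovitx_config_error")
  genes <- sprintf("R%06d", seq_len(n_ref))
  if (is.null(category_specs) || nrow(category_specs) == 0) {
    ann <- tibble(gene = character(), term = character(), term_name = character())
  } else {
    if (!all(c("term", "ref") %in% names(category_specs))) {
      abort("category_specs needs columns 'term' and 'ref'",
            class = "ovitx_config_error")
    }
    if (any(category_specs$ref > n_ref)) {
      bad <- category_specs$term[category_specs$ref > n_ref][1L]
      abort(sprintf("REF count for %s exceeds n_ref = %d", bad, n_ref),
            class = "ovitx_config_error")
    }
    if (!"term_name" %in% names(category_specs)) {
      category_specs$term_name <- category_specs$term
    }
    withr::local_seed(seed)
    ann <- purrr::pmap_dfr(
      category_specs[, c("term", "ref", "term_name")],
      function(term, ref, term_name) {
        tibble(gene = sample(genes, ref), term = term, term_name = term_name)
      })
  }
  go_universe(ann, n_ref, genes = genes)
}
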