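#' Per-setting inflation summary across genetic models
#'
#' @param results List of `gwas_result` objects (e.g. from
#'   [run_gwas_grid()]).
#' @return Data frame: one row per population setting, one column per
#'   genetic model, plus the per-setting `mean` over available models (a
#'   `flagged` column notes settings with missing models).
#' @export
summarize_inflation <- function(results) {
  if (!length(results)) stop("no GWAS results supplied")
  settings <- unique(vapply(results, `[[`, "", "setting"))
  models <- unique(vapply(results, `[[`, "", "model"))
  tab <- matrix(NA_real_, nrow = length(settings), ncol = length(models),
                dimnames = list(settings, models))
  for (r in results) tab[r$setting, r$model] <- r$inflation_factor
  out <- as.data.frame(tab)
  out$mean <- rowMeans(tab, na.rm = TRUE)
  out$flagged <- rowSums(is.na(tab)) > 0
  out <- cbind(setting = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline on a simulated or supplied panel
#'
#' Orchestrates the whole workflow: variant/sample filtering, LD pruning,
#' population structure (PCA, k-means/BIC, DAPC) and kinship with
#' leave-one-chromosome-out, phenotype BLUEs with Yeo-Johnson
#' normalisation, the full genetic-model x population-setting GWAS grid,
#' inflation summary and setting selection, FDR and high-scoring marker
#' extraction, optional differential-expression integration with
#' enrichment, and the HIDECAN layer table with colocalization windows.
#' A manifest records seeds, parameters and per-stage counts.
#'
#' @param config List with components:
#'   * `seed` (mandatory global seed),
#'   * either `geno` (a [geno_matrix()]) plus `scores` (bruising score data
#'     frame), or `simulate = TRUE` with `design`/`sim_config` to generate
#'     them,
#'   * optional `q_struct` membership matrix (e.g. imported from an
#'     admixture run); for simulated panels the truth-based membership is
#'     used when absent,
#'   * optional `counts`/`gene_coords` for the DE stage (simulated when
#'     `simulate` and `with_expression = TRUE`),
#'   * optional `candidates` data frame and `layout`
#'     ([chromosome_layout()]),
#'   * thresholds: `max_missing`, `min_qd`, `min_maf`, `window_bp`,
#'     `r2_threshold`, `alpha`, `marker_min_score`, `coloc_window_bp`,
#'   * `models` (default all eight), `out_dir` (optional; CSV outputs and
#'     `manifest.json` written there).
#' @return The manifest list (invisibly returns written paths in
#'   `manifest$outputs` when `out_dir` is set).
#' @export
run_end_to_end <- function(config) {
  cfg <- config
  if (is.null(cfg$seed)) stop("config$seed is mandatory")
  manifest <- list(seed = cfg$seed, stages = list())
  models <- cfg$models %||% genetic_models()
  alpha <- cfg$alpha %||% 0.05

  # -- stage 1: inputs ------------------------------------------------------
  truth <- NULL
  if (isTRUE(cfg$simulate)) {
    design <- cfg$design %||% default_cross_design()
    sim_cfg <- cfg$sim_config %||% simulation_config(
      pool_shift = 0.4, seed = stage_seed(cfg$seed, 1))
    panel <- simulate_panel(design, sim_cfg)
    g <- panel$geno
    truth <- panel$truth
    phen <- simulate_phenotype(
      subset_samples(g, truth$progeny),
      truth$qtl, h2 = sim_cfg$h2, config = sim_cfg,
      seed = stage_seed(cfg$seed, 2),
      polygenic_h2 = cfg$polygenic_h2 %||% 0.2)
    scores <- phen$scores
  } else {
    g <- cfg$geno
    scores <- cfg$scores
    if (is.null(g) || is.null(scores)) {
      stop("stage input: need geno + scores, or simulate = TRUE")
    }
  }
  manifest$stages$input <- list(n_samples = nrow(g$dosage),
                                n_markers = ncol(g$dosage))

  # -- stage 2: filtering ---------------------------------------------------
  g <- apply_sample_filter(g, cfg$max_missing %||% 0.10)
  g <- select_biallelic_het_snps(g)
  vf <- apply_variant_filters(g, max_missing = cfg$max_missing %||% 0.10,
                              min_qd = cfg$min_qd %||% 2,
                              min_maf = cfg$min_maf %||% 0.01)
  g <- vf$geno
  manifest$stages$filter <- vf$report

  # -- stage 3: LD pruning --------------------------------------------------
  pr <- prune_genome(g, window_bp = cfg$window_bp %||% 1e5,
                     r2_threshold = cfg$r2_threshold %||% 0.5,
                     seed = stage_seed(cfg$seed, 3))
  g <- apply_prune(g, pr)
  manifest$stages$prune <- list(retained = length(pr$retained),
                                dropped = nrow(pr$dropped),
                                seed = pr$seed)

  # -- stage 4: population structure + kinship ------------------------------
  n_pcs <- min(10, nrow(g$dosage) - 1, ncol(g$dosage))
  pca <- pca_dosage(g, n_components = n_pcs)
  cl <- select_n_clusters(pca$scores, nc_range = 1:10,
                          seed = stage_seed(cfg$seed, 4))
  q_dapc <- if (cl$n_clusters >= 2) {
    dapc_fit(pca$scores, cl$assignments,
             n_pcs = min(n_pcs, max(2, cl$n_clusters)))$membership
  } else {
    matrix(1, nrow = nrow(g$dosage), ncol = 1,
           dimnames = list(rownames(g$dosage), "C1"))
  }
  q_struct <- cfg$q_struct %||%
    (if (!is.null(truth)) truth_membership(list(geno = g, truth = truth))
     else q_dapc)
  q_struct <- q_struct[rownames(g$dosage), , drop = FALSE]
  K <- compute_kinship(g, loco = length(unique(g$info$chrom)) >= 2)
  manifest$stages$structure <- list(n_clusters = cl$n_clusters,
                                    n_pcs = n_pcs)

  # -- stage 5: phenotype ---------------------------------------------------
  blues <- compute_blues(scores)
  blues <- blues[blues$genotype %in% rownames(g$dosage), , drop = FALSE]
  norm <- yeo_johnson_standardize(blues$blue)
  y <- stats::setNames(norm$normalized, blues$genotype)
  g_phe <- subset_samples(g, names(y))
  K_phe <- compute_kinship(g_phe, loco = length(unique(g$info$chrom)) >= 2)
  manifest$stages$phenotype <- list(n_genotypes = length(y),
                                    lambda = norm$lambda)

  # -- stage 6: GWAS grid ---------------------------------------------------
  settings <- standard_settings(
    q_struct = q_struct[names(y), , drop = FALSE],
    q_dapc = q_dapc[names(y), , drop = FALSE])
  results <- run_gwas_grid(g_phe, y, settings, models = models, K = K_phe,
                           alpha = alpha)
  manifest$stages$gwas <- list(n_result_sets = length(results))

  # -- stage 7: inflation summary + setting selection -----------------------
  infl <- summarize_inflation(results)
  sel <- select_population_setting(stats::setNames(infl$mean, infl$setting))
  chosen <- results[vapply(results, `[[`, "", "setting") == sel$setting]
  manifest$stages$inflation <- list(table = infl, selected = sel$setting,
                                    below_one = sel$below_one)

  # -- stage 8: significant + high-scoring markers --------------------------
  significant <- unique(unlist(lapply(chosen, `[[`, "significant")))
  high <- unique(unlist(lapply(chosen, select_high_scoring,
                               min_score = cfg$marker_min_score %||% 4)))
  manifest$stages$markers <- list(n_significant = length(significant),
                                  n_high_scoring = length(high))

  # -- stage 9: DE integration (optional) -----------------------------------
  de <- NULL
  enrichment <- NULL
  counts <- cfg$counts
  if (is.null(counts) && isTRUE(cfg$simulate) &&
      isTRUE(cfg$with_expression)) {
    rep_means <- stats::aggregate(score ~ genotype, data = scores, FUN = mean)
    grp <- classify_bruising_groups(
      stats::setNames(rep_means$score, rep_means$genotype))
    grp <- grp[grp != "excluded"]
    if (sum(grp == "low") >= 2 && sum(grp == "high") >= 2) {
      sim_cfg2 <- cfg$sim_config %||% simulation_config(seed = cfg$seed)
      expr <- simulate_expression(grp, sim_cfg2,
                                  seed = stage_seed(cfg$seed, 9))
      counts <- expr$counts
      cfg$groups <- grp
      manifest$stages$expression_truth <- list(n_de = nrow(expr$truth))
      # place genes uniformly on the layout chromosomes for integration
      lay <- cfg$layout %||% chromosome_layout(
        unique(g$info$chrom),
        rep(max(g$info$pos) * 1.05, length(unique(g$info$chrom))))
      coords_rng <- with_seed(stage_seed(cfg$seed, 10), {
        chrs <- sample(lay$chrom, nrow(counts), replace = TRUE)
        st <- floor(stats::runif(nrow(counts)) *
                      lay$length_bp[match(chrs, lay$chrom)] * 0.98) + 1
        list(chrs = chrs, st = st)
      })
      chrs <- coords_rng$chrs
      st <- coords_rng$st
      cfg$gene_coords <- data.frame(gene_id = rownames(counts),
                                    chromosome = chrs, start = st,
                                    end = st + 2000)
    }
  }
  if (!is.null(counts) && !is.null(cfg$groups)) {
    counts <- filter_low_expression(counts)
    coords <- cfg$gene_coords
    if (!is.null(coords)) {
      coords <- coords[match(rownames(counts), coords$gene_id), , drop = FALSE]
    }
    de <- simple_de_test(counts, cfg$groups, coords = coords)
    de_sets <- significant_de(de, alpha = alpha)
    manifest$stages$de <- list(n_genes = nrow(de),
                               n_up = length(de_sets$up),
                               n_down = length(de_sets$down))
    if (!is.null(cfg$gene_sets)) {
      enrichment <- fcs_enrichment(de_gene_scores(de), cfg$gene_sets)
      manifest$stages$enrichment <-
        list(n_sets = nrow(enrichment),
             n_enriched = sum(enrichment$adjusted_p < alpha, na.rm = TRUE))
    }
  }

  # -- stage 10: HIDECAN ----------------------------------------------------
  layout <- cfg$layout %||% chromosome_layout(
    unique(g$info$chrom),
    vapply(unique(g$info$chrom), function(ch) {
      max(g$info$pos[g$info$chrom == ch]) * 1.05
    }, numeric(1)))
  hd <- build_hidecan_data(gwas = chosen, de = de,
                           candidates = cfg$candidates, layout = layout,
                           marker_min_score = cfg$marker_min_score %||% 4,
                           de_alpha = alpha)
  coloc <- colocalization_windows(hd,
                                  window_bp = cfg$coloc_window_bp %||% 1e6)
  manifest$stages$hidecan <- list(n_rows = nrow(hd),
                                  n_coloc_regions = nrow(coloc))

  manifest$results <- list(gwas = results, inflation = infl,
                           selected_setting = sel, significant = significant,
                           high_scoring = high, de = de,
                           enrichment = enrichment, hidecan = hd,
                           colocalization = coloc, truth = truth,
                           phenotype = y, geno = g_phe, kinship = K_phe)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      hidecan = file.path(cfg$out_dir, "hidecan_data.csv"),
      inflation = file.path(cfg$out_dir, "inflation.csv"),
      manifest = file.path(cfg$out_dir, "manifest.json"))
    utils::write.csv(as.data.frame(hd), paths["hidecan"], row.names = FALSE)
    utils::write.csv(infl, paths["inflation"], row.names = FALSE)
    slim <- manifest
    slim$results <- NULL
    jsonlite::write_json(slim, paths["manifest"], auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    manifest$outputs <- paths
  }
  manifest
}
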