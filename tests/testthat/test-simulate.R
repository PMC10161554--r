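test_that("tetraploid meiosis follows the hypergeometric gamete model", {
  # 0 x 0 parents give all-zero progeny
  off0 <- simulate_cross(rep(0, 5), rep(0, 5), 10, seed = 1)
  expect_true(all(off0 == 0))
  off8 <- simulate_cross(rep(4, 5), rep(4, 5), 10, seed = 1)
  expect_true(all(off8 == 4))
  expect_error(simulate_cross(5, 0, 3), "0..4")

  # duplex x duplex offspring pmf: convolution of {1,4,1}/6 with itself
  off <- simulate_cross(2, 2, 10000, seed = 7)
  expected_pmf <- c(1, 8, 18, 8, 1) / 36
  obs <- tabulate(off + 1, nbins = 5)
  gof <- chisq.test(obs, p = expected_pmf)
  expect_gt(gof$p.value, 0.01)

  # Mendelian conservation: mean progeny dosage = mid-parent dosage
  off13 <- simulate_cross(1, 3, 10000, seed = 9)
  expect_equal(mean(off13), 2, tolerance = 0.05)

  # determinism under a fixed seed
  a <- simulate_cross(c(1, 2, 3), c(2, 2, 4), 20, seed = 5)
  b <- simulate_cross(c(1, 2, 3), c(2, 2, 4), 20, seed = 5)
  expect_identical(a, b)
})

test_that("the default half-sib design reproduces the published panel scale", {
  design <- default_cross_design()
  expect_equal(nrow(design), 23)
  expect_equal(sum(design$n_progeny), 158)
  expect_equal(length(unique(design$parent1)), 2)
})

test_that("panel simulation emits consistent genotypes, truth and structure", {
  cfg <- simulation_config(n_chromosomes = 3, markers_per_chromosome = 30,
                           pool_shift = 0.5, missing_rate = 0.02,
                           qtl = data.frame(chrom_index = 2,
                                            marker_index = 10,
                                            model = "additive", effect = 1),
                           seed = 33)
  panel <- simulate_panel(default_cross_design(), cfg)
  g <- panel$geno
  expect_equal(length(panel$truth$progeny), 158)
  expect_true(all(g$dosage >= 0 & g$dosage <= 4, na.rm = TRUE))
  expect_true(all(g$dosage == round(g$dosage), na.rm = TRUE))
  expect_gt(mean(is.na(g$dosage)), 0.005)
  expect_lt(mean(is.na(g$dosage)), 0.05)
  expect_true(panel$truth$qtl$marker %in% g$info$marker)

  # same seed, byte-identical output
  panel2 <- simulate_panel(default_cross_design(), cfg)
  expect_identical(panel2$geno$dosage, g$dosage)

  # no missing entries at rate 0
  cfg0 <- simulation_config(seed = 34, missing_rate = 0)
  p0 <- simulate_panel(default_cross_design(), cfg0)
  expect_false(anyNA(p0$geno$dosage))

  expect_error(simulate_panel(data.frame(parent1 = "a", parent2 = "b",
                                         n_progeny = 0), cfg),
               "zero total progeny")
})

test_that("progeny allele frequencies match mid-parent expectations", {
  cfg <- simulation_config(n_chromosomes = 2, markers_per_chromosome = 40,
                           seed = 35)
  design <- data.frame(parent1 = "A", parent2 = "B", n_progeny = 300)
  panel <- simulate_panel(design, cfg)
  prog <- panel$geno$dosage[panel$truth$progeny, ]
  pd <- panel$truth$parent_dosage
  mid <- (pd["A", ] + pd["B", ]) / 8          # expected allele frequency
  mid <- mid[colnames(prog)]
  obs <- colMeans(prog) / 4
  se <- sqrt(mid * (1 - mid) / (4 * 300))
  expect_true(all(abs(obs - mid) <= pmax(3 * se, 1e-9) + 0.02))
})

test_that("diverged founder pools create recoverable population structure", {
  cfg <- simulation_config(n_chromosomes = 2, markers_per_chromosome = 100,
                           pool_shift = 0.5, seed = 36)
  design <- data.frame(parent1 = c("A", "B"), parent2 = c("C", "D"),
                       n_progeny = c(60, 60))
  panel <- simulate_panel(design, cfg)
  prog <- subset_samples(panel$geno, panel$truth$progeny)
  pools <- panel$truth$subpop[panel$truth$progeny]
  pc <- pca_dosage(prog, 2)
  # silhouette of the true pool labels on PC1-2
  x <- pc$scores
  sil <- vapply(seq_len(nrow(x)), function(i) {
    own <- pools == pools[i]
    a <- mean(sqrt(rowSums((x[own & seq_len(nrow(x)) != i, , drop = FALSE] -
                              rep(x[i, ], each = sum(own) - 1))^2)))
    b <- mean(sqrt(rowSums((x[!own, , drop = FALSE] -
                              rep(x[i, ], each = sum(!own)))^2)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})

test_that("phenotype simulation hits the requested QTL variance share", {
  cfg <- simulation_config(n_chromosomes = 2, markers_per_chromosome = 50,
                           seed = 37)
  design <- data.frame(parent1 = "A", parent2 = "B", n_progeny = 200)
  panel <- simulate_panel(design, cfg)
  g <- subset_samples(panel$geno, panel$truth$progeny)
  qtl <- data.frame(marker = g$info$marker[10], model = "additive",
                    effect = 1)
  hits <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    phe <- simulate_phenotype(g, qtl, h2 = 0.2, config = cfg, seed = 100 + r)
    x <- g$dosage[, 10]
    r2 <- summary(lm(phe$latent ~ x))$r.squared
    if (r2 >= 0.1 && r2 <= 0.3) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)

  # discretised scores live on the 0-5 scale
  phe <- simulate_phenotype(g, qtl, h2 = 0.2, config = cfg, seed = 1)
  expect_true(all(phe$scores$score %in% 0:5))
  expect_equal(nrow(phe$scores), 200 * cfg$n_replicates * cfg$n_tubers)

  # h2 = 0: latent value independent of the QTL marker
  phe0 <- simulate_phenotype(g, qtl, h2 = 0, config = cfg, seed = 2)
  expect_gt(summary(lm(phe0$latent ~ g$dosage[, 10]))$coefficients[2, 4],
            0.001)
  expect_error(simulate_phenotype(g, qtl, h2 = 1.2, config = cfg), "0, 1")
})

test_that("expression simulation plants DE genes at the configured fold change", {
  groups <- setNames(rep(c("low", "high"), c(41, 33)), paste0("s", 1:74))
  cfg <- simulation_config(n_genes = 500, n_de = 57, de_log2fc = 2,
                           nb_dispersion = 0.1, seed = 38)
  sim <- simulate_expression(groups, cfg, seed = 39)
  expect_equal(dim(sim$counts), c(500, 74))
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == round(sim$counts)))
  expect_equal(nrow(sim$truth), 57)

  # planted genes shift in the planted direction
  lo <- names(groups)[groups == "low"]
  hi <- names(groups)[groups == "high"]
  lfc <- log2((rowMeans(sim$counts[, hi]) + 1) /
                (rowMeans(sim$counts[, lo]) + 1))
  planted_up <- sim$truth$gene_id[sim$truth$direction > 0]
  expect_gt(mean(lfc[planted_up]), 1)

  # Poisson limit: variance/mean ratio near 1 when dispersion is 0
  cfgp <- simulation_config(n_genes = 1, n_de = 0, nb_dispersion = 0,
                            seed = 40)
  gp <- setNames(rep(c("low", "high"), each = 5000), paste0("t", 1:10000))
  simp <- simulate_expression(gp, cfgp, seed = 41)
  ratio <- var(as.numeric(simp$counts[1, ])) / mean(simp$counts[1, ])
  # library-size spread adds a little extra-Poisson variance; compare
  # within a single size factor by regenerating with a flat range
  cfgf <- simulation_config(n_genes = 1, n_de = 0, nb_dispersion = 0,
                            libsize_range = c(1, 1), seed = 42)
  simf <- simulate_expression(gp, cfgf, seed = 43)
  ratio_f <- var(as.numeric(simf$counts[1, ])) / mean(simf$counts[1, ])
  expect_gt(ratio_f, 0.9)
  expect_lt(ratio_f, 1.1)

  expect_error(simulate_expression(groups,
                                   simulation_config(n_genes = 5, n_de = 6,
                                                     seed = 1)),
               "exceed")
})
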