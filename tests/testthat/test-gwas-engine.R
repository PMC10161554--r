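make_panel_fixture <- function(n = 60, m = 40, n_chr = 2, seed = 1) {
  with_seed(seed, {
    d <- matrix(rbinom(n * m, 4, runif(m, 0.2, 0.8)[rep(seq_len(m),
                                                        each = n)]),
                nrow = n)
    toy_geno(d, chrom = rep(paste0("chr", seq_len(n_chr)), each = m / n_chr),
             pos = rep(seq_len(m / n_chr) * 1e4, n_chr))
  })
}

test_that("the REML optimum matches a brute-force grid on a small instance", {
  set.seed(21)
  n <- 12
  A <- matrix(rnorm(n * n), n)
  K <- tcrossprod(A) / n
  K <- K / mean(diag(K))
  L <- t(chol(K + 1e-8 * diag(n)))
  y <- drop(L %*% rnorm(n)) * sqrt(3) + rnorm(n)
  names(y) <- paste0("s", 1:n)
  ks <- structure(list(global = K, per_chromosome = NULL,
                       samples = names(y)), class = "kinship_set")
  st <- population_setting("K", TRUE)
  fit <- fit_null_model(y, st, K = ks)

  # independent grid over the variance ratio using the same REML criterion
  # assembled from scratch (dense matrix algebra, no eigen shortcut)
  crit <- function(lambda) {
    V <- lambda * K + diag(n)
    Vi <- solve(V)
    X <- matrix(1, n, 1)
    XtVX <- t(X) %*% Vi %*% X
    beta <- solve(XtVX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    rss <- drop(t(r) %*% Vi %*% r)
    (n - 1) * log(rss) + determinant(V)$modulus + log(det(XtVX))
  }
  grid <- exp(seq(log(1e-3), log(1e3), length.out = 4000))
  vals <- vapply(grid, crit, numeric(1))
  lambda_grid <- grid[which.min(vals)]
  expect_equal(log(fit$lambda), log(lambda_grid), tolerance = 0.01)
  expect_gte(fit$sigma2_g, 0)
  expect_gte(fit$sigma2_e, 0)
})

test_that("variance-ratio recovery works on simulated kinship data", {
  set.seed(22)
  n <- 200
  reps <- 20
  ok <- 0
  for (r in seq_len(reps)) {
    A <- matrix(rnorm(n * 50), n)
    K <- tcrossprod(scale(A, scale = FALSE))
    K <- K / mean(diag(K))
    L <- with(eigen(K, symmetric = TRUE),
              vectors %*% diag(sqrt(pmax(values, 0))))
    y <- drop(L %*% rnorm(n)) * sqrt(3) + rnorm(n)
    names(y) <- paste0("s", 1:n)
    ks <- structure(list(global = K, per_chromosome = NULL,
                         samples = names(y)), class = "kinship_set")
    fit <- fit_null_model(y, population_setting("K", TRUE), K = ks)
    if (abs(fit$lambda - 3) / 3 < 0.5) ok <- ok + 1
  }
  expect_gte(ok / reps, 0.7)
})

test_that("naive-setting scores equal plain OLS F-tests for every model", {
  g <- make_panel_fixture(n = 50, m = 20, seed = 31)
  set.seed(32)
  y <- setNames(rnorm(50), rownames(g$dosage))
  naive <- population_setting("naive", FALSE)
  for (mod in genetic_models()) {
    res <- score_markers(g, y, mod, naive)
    for (j in seq_len(20)) {
      row <- res$scores[j, ]
      if (!is.na(row$skipped_reason)) next
      S <- encode_dosage(mod, g$dosage[names(y), j])
      ols <- ols_score_oracle(y, NULL, S)
      expect_equal(row$score, ols, tolerance = 1e-6,
                   label = paste(mod, "marker", j))
    }
  }
})

test_that("a noise-free additive marker dominates and degenerate markers are skipped", {
  g <- make_panel_fixture(n = 50, m = 20, seed = 41)
  d <- g$dosage
  d[, 5] <- rep(0:4, each = 10)        # the causal column
  d[, 7] <- 2                          # monomorphic
  g <- toy_geno(d, chrom = g$info$chrom, pos = g$info$pos)
  y <- setNames(as.numeric(d[, 5]), rownames(d))
  res <- score_markers(g, y, "additive", population_setting("naive", FALSE))
  expect_equal(which.max(res$scores$score), 5)
  expect_equal(res$scores$skipped_reason[7], "constant_encoding")
  expect_true(is.na(res$scores$score[7]))
  expect_true(all(res$scores$score >= 0, na.rm = TRUE))
})

test_that("inflation factor is the origin regression on expected null quantiles", {
  m <- 200
  expected <- -log10(seq_len(m) / (m + 1))
  expect_equal(inflation_factor(expected), 1.0)
  expect_equal(inflation_factor(2 * expected), 2.0)
  expect_error(inflation_factor(rep(1, 50)), "all scores equal")
  expect_error(inflation_factor(1:5), "at least 10")
})

test_that("inflation is calibrated on uniform null p-values", {
  set.seed(51)
  reps <- 200
  inside <- 0
  for (r in seq_len(reps)) {
    lam <- inflation_factor(-log10(runif(5000)))
    if (lam >= 0.95 && lam <= 1.05) inside <- inside + 1
  }
  expect_gte(inside / reps, 0.95)
})

test_that("population-setting selection follows the closest-above-one rule", {
  expect_equal(
    select_population_setting(c(A = 1.53, B = 1.13, C = 1.08))$setting, "C")
  sel <- select_population_setting(c(A = 1.5, B = 0.95, C = 1.05))
  expect_equal(sel$setting, "C")
  expect_false(sel$below_one)
  fallback <- select_population_setting(c(A = 0.9, B = 0.8))
  expect_equal(fallback$setting, "A")
  expect_true(fallback$below_one)
  expect_error(select_population_setting(numeric(0)), "no inflation")
})

test_that("the FDR threshold matches the hand-worked Benjamini-Hochberg case", {
  p <- c(0.005, 0.009, 0.02, 0.4, 0.9)
  res <- fdr_score_threshold(p, alpha = 0.05)
  expect_equal(res$n_significant, 3)
  expect_equal(res$threshold, -log10(0.02))
  expect_equal(fdr_score_threshold(rep(1, 4))$n_significant, 0)
  expect_equal(fdr_score_threshold(rep(1, 4))$threshold, Inf)
  expect_equal(fdr_score_threshold(0.04, alpha = 0.05)$n_significant, 1)
  # agreement with p.adjust on random vectors
  set.seed(61)
  for (r in 1:10) {
    pv <- runif(50)^2
    res <- fdr_score_threshold(pv, alpha = 0.05)
    expect_equal(res$n_significant,
                 sum(p.adjust(pv, "BH") <= 0.05 + 1e-12))
  }
})

test_that("high-scoring selection is strict at the score threshold", {
  s <- c(a = 4.01, b = 4.0, c = 7, d = NA, e = 2)
  expect_equal(select_high_scoring(s), c("a", "c"))
  expect_length(select_high_scoring(numeric(0)), 0)
})

test_that("null high-scoring counts respect the binomial bound", {
  set.seed(71)
  counts <- replicate(50, sum(-log10(runif(10000)) > 4))
  expect_lte(mean(counts > 6), 0.01)
})

test_that("score correlations are symmetric and cluster near-identical settings", {
  g <- make_panel_fixture(n = 60, m = 30, seed = 81)
  set.seed(82)
  y <- setNames(rnorm(60), rownames(g$dosage))
  # a near-no-op covariate: phenotype-independent membership jitter
  eps <- rnorm(60, sd = 0.01)
  q_noop <- cbind(A = 0.5 + eps, B = 0.5 - eps)
  rownames(q_noop) <- names(y)
  r1 <- score_markers(g, y, "additive", population_setting("naive", FALSE))
  r2 <- score_markers(g, y, "additive",
                      population_setting("noop", FALSE, q_noop))
  r3 <- score_markers(g, y, "general", population_setting("naive", FALSE))
  cc <- score_correlation_matrix(list(r1, r2, r3))
  expect_equal(diag(cc$correlation), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cc$correlation, t(cc$correlation))
  expect_gt(cc$correlation[1, 2], 0.99)
  expect_error(score_correlation_matrix(list(r1)), "at least 2")
})

test_that("the full model-by-setting grid yields 48 result sets", {
  g <- make_panel_fixture(n = 40, m = 20, seed = 91)
  set.seed(92)
  y <- setNames(rnorm(40), rownames(g$dosage))
  q <- matrix(runif(80), ncol = 2)
  q <- q / rowSums(q)
  rownames(q) <- names(y)
  K <- compute_kinship(g, loco = TRUE)
  grid <- run_gwas_grid(g, y, standard_settings(q, q), K = K)
  expect_length(grid, 48)
  expect_setequal(unique(vapply(grid, `[[`, "", "model")), genetic_models())
})
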