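test_that("dosage PCA centres, conserves variance, and places progeny midway", {
  set.seed(3)
  d <- matrix(sample(0:4, 20 * 50, replace = TRUE), nrow = 20)
  d[2, ] <- d[1, ]  # duplicated sample
  g <- toy_geno(d)
  pc <- pca_dosage(g, n_components = 5)
  expect_equal(pc$scores[1, ], pc$scores[2, ])
  expect_lte(sum(pc$explained), 1 + 1e-12)
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_error(pca_dosage(g, n_components = 100), "exceeds")

  # exact-midpoint progeny lies halfway between its parents in PC space
  p1 <- sample(0:4, 50, replace = TRUE)
  p2 <- sample(0:4, 50, replace = TRUE)
  fam <- rbind(p1, p2, (p1 + p2) / 2,
               matrix(sample(0:4, 50 * 7, replace = TRUE), nrow = 7))
  gf <- toy_geno(fam, dosage_kind = "posterior_mean")
  pcf <- pca_dosage(gf, n_components = 3)
  expect_equal(pcf$scores[3, ],
               (pcf$scores[1, ] + pcf$scores[2, ]) / 2, tolerance = 1e-8)
})

test_that("BIC selects the planted number of k-means clusters", {
  # separation on two axes, within-cluster spread over many dimensions, as
  # with PCA scores of genotype panels where most retained components carry
  # noise that further splits cannot reduce
  set.seed(5)
  d <- 60
  centers <- matrix(0, 3, d)
  centers[2, 1] <- 15
  centers[3, 2] <- 15
  x <- do.call(rbind, lapply(1:3, function(i) {
    sweep(matrix(rnorm(50 * d), ncol = d), 2, centers[i, ], "+")
  }))
  sel <- select_n_clusters(x, nc_range = 1:8, seed = 7)
  expect_equal(sel$n_clusters, 3)
  expect_equal(unname(which.min(sel$bic_curve)), 3)
  # duplicating every sample leaves the selection unchanged
  sel2 <- select_n_clusters(rbind(x, x), nc_range = 1:8, seed = 7)
  expect_equal(sel2$n_clusters, 3)
})

test_that("DAPC memberships are row-stochastic and separate planted clusters", {
  set.seed(6)
  centers <- rbind(c(0, 0, 0), c(15, 0, 0), c(0, 15, 0))
  x <- do.call(rbind, lapply(1:3, function(i) {
    sweep(matrix(rnorm(120), ncol = 3), 2, centers[i, ], "+")
  }))
  grp <- rep(1:3, each = 40)
  fit <- dapc_fit(x, grp, n_pcs = 3)
  expect_equal(unname(rowSums(fit$membership)), rep(1, 120))
  expect_true(all(apply(fit$membership, 1, max) > 0.99))
  expect_equal(ncol(fit$discriminant_axes), min(3 - 1, 3))
  expect_error(dapc_fit(x, c(rep(1, 119), 2), n_pcs = 2), "fewer than 2")
})

test_that("cross-validation scores DAPC PC counts and respects bounds", {
  set.seed(8)
  centers <- rbind(c(0, 0, 0, 0), c(12, 0, 0, 0), c(0, 12, 0, 0))
  x <- do.call(rbind, lapply(1:3, function(i) {
    sweep(matrix(rnorm(160), ncol = 4), 2, centers[i, ], "+")
  }))
  grp <- rep(1:3, each = 40)
  cv <- dapc_cross_validate(x, grp, n_pcs_grid = 2:4, n_reps = 5, seed = 3)
  expect_true(all(cv$cv_curve$accuracy >= 0 & cv$cv_curve$accuracy <= 1))
  expect_true(all(cv$cv_curve$rmse >= 0 & cv$cv_curve$rmse <= 1))
  expect_true(all(cv$cv_curve$accuracy[cv$cv_curve$n_pcs >= 2] > 0.95))
  expect_error(dapc_cross_validate(x, grp, 2:3, n_reps = 0), "n_reps")

  # permuting cluster labels leaves accuracy invariant
  relab <- c("1" = "b", "2" = "c", "3" = "a")[as.character(grp)]
  cv2 <- dapc_cross_validate(x, relab, n_pcs_grid = 2:4, n_reps = 5, seed = 3)
  expect_equal(cv2$cv_curve$accuracy, cv$cv_curve$accuracy, tolerance = 1e-12)
})

test_that("Evanno delta reproduces the hand-computed second difference", {
  ll <- list("1" = c(-100, -100), "2" = c(-49, -51), "3" = c(-48, -48.2),
             "4" = c(-47, -47))
  d <- evanno_delta(ll)
  expect_equal(names(d), c("2", "3"))
  sd2 <- sd(c(-49, -51))
  expect_equal(unname(d["2"]),
               abs(mean(c(-48, -48.2)) - 2 * (-50) + (-100)) / sd2)
  # linear likelihood profile gives zero delta at interior points
  lin <- list("1" = c(-30, -30 + 1e-3), "2" = c(-20, -20 + 1e-3),
              "3" = c(-10, -10 + 1e-3))
  expect_equal(unname(evanno_delta(lin)["2"]), 0, tolerance = 1e-6)
  # zero replicate sd is undefined, not an error
  const <- list("1" = c(-9, -9), "2" = c(-5, -5), "3" = c(-2, -2))
  expect_true(is.na(evanno_delta(const)["2"]))
})

test_that("run alignment undoes label switching and averages noisy runs", {
  set.seed(9)
  base <- matrix(rgamma(60 * 4, 2), ncol = 4)
  base <- base / rowSums(base)
  expect_equal(align_structure_runs(list(base, base)), base)
  perm <- base[, c(3, 1, 4, 2)]
  expect_equal(align_structure_runs(list(base, perm)), base)

  # noisy perturbations: recovered average stays near the original and the
  # chosen permutation matches an exhaustive-assignment oracle
  noisy <- lapply(1:5, function(i) {
    p <- sample(4)
    run <- base[, p] * matrix(rgamma(60 * 4, 50, 50), ncol = 4)
    run / rowSums(run)
  })
  avg <- align_structure_runs(c(list(base), noisy))
  expect_lt(max(abs(avg - base)), 0.05)

  exhaustive_best <- function(ref, run) {
    perms <- list(); grid <- expand.grid(rep(list(1:4), 4))
    best <- NULL; best_s <- -Inf
    for (r in seq_len(nrow(grid))) {
      p <- unlist(grid[r, ])
      if (length(unique(p)) != 4) next
      s <- sum(diag(suppressWarnings(stats::cor(ref, run[, p]))))
      if (s > best_s) { best_s <- s; best <- p }
    }
    best
  }
  for (run in noisy[1:2]) {
    p_oracle <- exhaustive_best(base, run)
    aligned <- align_structure_runs(list(base, run))
    manual <- (base + run[, p_oracle]) / 2
    manual <- manual / rowSums(manual)
    expect_equal(aligned, manual, tolerance = 1e-12)
  }

  bad <- list(base, base[, 1:3] / rowSums(base[, 1:3]))
  expect_error(align_structure_runs(bad), "same number of groups")
})

test_that("kinship is a scaled MM^T with working leave-one-chromosome-out", {
  set.seed(10)
  d <- matrix(sample(0:4, 30 * 80, replace = TRUE), nrow = 30)
  d[2, ] <- d[1, ]
  g <- toy_geno(d, chrom = rep(c("chr1", "chr2"), each = 40))
  K <- compute_kinship(g, loco = TRUE)
  expect_equal(mean(diag(K$global)), 1)
  expect_equal(K$global[1, ], K$global[2, ])
  expect_equal(max(abs(K$global - t(K$global))), 0)
  ev <- eigen(K$global, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))

  # LOCO for chr1 equals kinship built from chr2 markers alone
  g2 <- subset_markers(g, which(g$info$chrom == "chr2"))
  K2 <- compute_kinship(g2, loco = FALSE)
  expect_equal(K$per_chromosome[["chr1"]], K2$global, tolerance = 1e-12)

  g1 <- subset_markers(g, which(g$info$chrom == "chr1"))
  expect_error(compute_kinship(g1, loco = TRUE), "2 chromosomes")
})

test_that("STRUCTURE export/import round-trips dosages and memberships", {
  d <- rbind(c(0, 2, 4), c(1, NA, 3))
  g <- toy_geno(d)
  path <- withr::local_tempfile()
  export_structure(g, path)
  lines <- readLines(path)
  expect_length(lines, 1 + 2 * 4)
  first_sample <- do.call(rbind, strsplit(lines[2:5], " "))
  # alternate-allele counts per marker recover the dosage
  recovered <- colSums(first_sample[, -1] == "1")
  expect_equal(unname(recovered), c(0, 2, 4))
  expect_true(all(strsplit(lines[6], " ")[[1]][3] == "-9"))

  out <- withr::local_tempfile()
  writeLines(c(
    "Estimated Ln Prob of Data = -1234.5",
    "Inferred ancestry of individuals:",
    "  1 sampA (0) : 0.90 0.10",
    "  2 sampB (2) : 0.25 0.75"
  ), out)
  imp <- import_structure(out)
  expect_equal(imp$log_likelihood, -1234.5)
  expect_equal(unname(imp$membership["sampA", ]), c(0.9, 0.1))
  expect_equal(unname(rowSums(imp$membership)), c(1, 1))
})

test_that("marker subsampling is deterministic and order-preserving", {
  g <- toy_geno(matrix(sample(0:4, 10 * 30, replace = TRUE), nrow = 10))
  s1 <- subsample_markers(g, 10, seed = 4)
  s2 <- subsample_markers(g, 10, seed = 4)
  expect_identical(s1$info$marker, s2$info$marker)
  expect_identical(s1$info$pos, sort(s1$info$pos))
  expect_equal(ncol(s1$dosage), 10)
})
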