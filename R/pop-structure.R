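#' PCA on allele dosages
#'
#' Missing dosages are mean-imputed per marker, columns are centred (not
#' scaled) and a standard PCA is computed.
#'
#' @param g A [geno_matrix()].
#' @param n_components Number of components to return.
#' @return List with `scores` (samples x components), `explained` (variance
#'   proportion per component), `sdev` and `center`.
#' @export
pca_dosage <- function(g, n_components = 10) {
  d <- impute_column_means(g$dosage)
  if (nrow(d) < 2) stop("PCA requires at least 2 samples")
  kmax <- min(nrow(d) - 1, ncol(d))
  if (n_components > min(nrow(d), ncol(d))) {
    stop("n_components exceeds min(n_samples, n_markers)")
  }
  n_components <- min(n_components, kmax)
  pc <- stats::prcomp(d, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  list(scores = scores,
       explained = pc$sdev^2 / sum(pc$sdev^2),
       sdev = pc$sdev,
       center = pc$center)
}

impute_column_means <- function(d) {
  if (!anyNA(d)) return(d)
  mu <- colMeans(d, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2]]
  d
}

#' Choose the number of k-means clusters by BIC
#'
#' Runs k-means on the PCA scores for each candidate cluster count and scores
#' each solution with `BIC(k) = n log(WSS/n) + k log(n)` (the convention of
#' DAPC-style find-clusters procedures). The smallest cluster count attaining
#' the minimum BIC is returned.
#'
#' @param pca_scores Numeric matrix of PCA scores (samples x components).
#' @param nc_range Candidate cluster counts (default 1..10).
#' @param seed Integer seed for the k-means starts.
#' @param nstart Number of random k-means starts per candidate.
#' @return List with `n_clusters`, `bic_curve` (named numeric) and
#'   `assignments` (cluster labels at the selected count).
#' @export
select_n_clusters <- function(pca_scores, nc_range = 1:10, seed = 1,
                              nstart = 10) {
  x <- as.matrix(pca_scores)
  n <- nrow(x)
  if (max(nc_range) >= n) {
    warning("cluster range restricted to n_samples - 1")
    nc_range <- nc_range[nc_range < n]
  }
  fits <- with_seed(seed, lapply(nc_range, function(k) {
    stats::kmeans(x, centers = k, nstart = nstart, iter.max = 50)
  }))
  bic <- vapply(seq_along(nc_range), function(i) {
    wss <- fits[[i]]$tot.withinss
    n * log(wss / n) + nc_range[i] * log(n)
  }, numeric(1))
  names(bic) <- nc_range
  best <- nc_range[which.min(bic)]  # which.min takes the first = smallest k
  list(n_clusters = best, bic_curve = bic,
       assignments = fits[[match(best, nc_range)]]$cluster)
}

#' Discriminant analysis of principal components
#'
#' Fits a linear discriminant analysis on the first `n_pcs` PCA scores with
#' equal priors; memberships are the Gaussian posteriors under the pooled
#' within-cluster covariance, i.e. a soft assignment in discriminant space.
#'
#' @param pca_scores PCA scores matrix.
#' @param cluster_assignments Per-sample cluster labels.
#' @param n_pcs Number of leading PCs fed to the discriminant analysis.
#' @return A `dapc_model`: list with `n_pcs_retained`, `cluster_count`,
#'   `cluster_assignments`, `discriminant_axes`, `membership` (rows sum to 1)
#'   and the fitted `lda` object.
#' @export
dapc_fit <- function(pca_scores, cluster_assignments, n_pcs) {
  x <- as.matrix(pca_scores)
  if (n_pcs > ncol(x)) stop("n_pcs exceeds available principal components")
  grp <- factor(cluster_assignments)
  k <- nlevels(grp)
  if (k < 2) stop("discriminant analysis needs at least 2 clusters")
  sizes <- table(grp)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    stop("cluster(s) with fewer than 2 members: ",
         paste(small, collapse = ", "))
  }
  xr <- x[, seq_len(n_pcs), drop = FALSE]
  fit <- MASS::lda(xr, grouping = grp, prior = rep(1 / k, k))
  post <- stats::predict(fit, xr)$posterior
  rownames(post) <- rownames(x)
  structure(list(
    n_pcs_retained = n_pcs,
    cluster_count = k,
    cluster_assignments = grp,
    discriminant_axes = fit$scaling,
    membership = post / rowSums(post),
    lda = fit
  ), class = "dapc_model")
}

#' Cross-validate the number of retained PCs for DAPC
#'
#' For each candidate PC count, repeats a stratified 90/10 split: the
#' discriminant analysis is fitted on the training 90% and scored on the
#' held-out 10% by assignment accuracy and by the RMSE between the posterior
#' membership and the 0/1 truth. The PC count maximising mean accuracy is
#' selected, ties going to the smaller count.
#'
#' @param pca_scores PCA scores matrix.
#' @param cluster_assignments Per-sample cluster labels.
#' @param n_pcs_grid Candidate PC counts.
#' @param n_reps Number of random splits per candidate.
#' @param seed Integer seed.
#' @param train_fraction Fraction of each cluster assigned to training.
#' @return List with `cv_curve` (data frame: n_pcs, accuracy, rmse) and
#'   `selected_n_pcs`.
#' @export
dapc_cross_validate <- function(pca_scores, cluster_assignments, n_pcs_grid,
                                n_reps = 30, seed = 1,
                                train_fraction = 0.9) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  x <- as.matrix(pca_scores)
  grp <- factor(cluster_assignments)
  k <- nlevels(grp)
  n_pcs_grid <- sort(unique(n_pcs_grid))
  res <- with_seed(seed, {
    lapply(n_pcs_grid, function(p) {
      acc <- rmse <- numeric(n_reps)
      for (r in seq_len(n_reps)) {
        train <- unlist(lapply(levels(grp), function(g) {
          idx <- which(grp == g)
          n_tr <- max(2, floor(train_fraction * length(idx)))
          n_tr <- min(n_tr, length(idx) - 1)
          if (n_tr < 2) stop("cluster '", g, "' too small for a 90/10 split")
          sample(idx, n_tr)
        }))
        test <- setdiff(seq_len(nrow(x)), train)
        fit <- MASS::lda(x[train, seq_len(p), drop = FALSE],
                         grouping = grp[train], prior = rep(1 / k, k))
        pr <- stats::predict(fit, x[test, seq_len(p), drop = FALSE])
        acc[r] <- mean(pr$class == grp[test])
        truth <- outer(as.character(grp[test]),
                       colnames(pr$posterior), "==") * 1
        rmse[r] <- sqrt(mean((pr$posterior - truth)^2))
      }
      c(accuracy = mean(acc), rmse = mean(rmse))
    })
  })
  curve <- data.frame(n_pcs = n_pcs_grid,
                      accuracy = vapply(res, `[[`, 0, "accuracy"),
                      rmse = vapply(res, `[[`, 0, "rmse"))
  sel <- curve$n_pcs[which.max(curve$accuracy)]  # first max = smallest n_pcs
  list(cv_curve = curve, selected_n_pcs = sel)
}

#' Evanno second-derivative statistic for admixture run likelihoods
#'
#' For consecutive subpopulation counts, computes
#' `delta(k) = |mean L(k+1) - 2 mean L(k) + mean L(k-1)| / sd(L(k))` from the
#' replicate log-likelihoods. Endpoints have no delta; a zero replicate
#' standard deviation makes the statistic undefined (`NA`) for that count.
#'
#' @param log_likelihoods Named list mapping subpopulation count to a numeric
#'   vector of replicate likelihoods (names must be consecutive integers).
#' @return Named numeric vector of delta values for interior counts.
#' @export
evanno_delta <- function(log_likelihoods) {
  ks <- sort(as.integer(names(log_likelihoods)))
  if (length(ks) < 3) stop("need likelihoods for at least 3 consecutive counts")
  if (any(diff(ks) != 1)) stop("subpopulation counts must be consecutive")
  mu <- vapply(as.character(ks), function(k) mean(log_likelihoods[[k]]),
               numeric(1))
  sds <- vapply(as.character(ks), function(k) stats::sd(log_likelihoods[[k]]),
                numeric(1))
  inner <- ks[-c(1, length(ks))]
  delta <- vapply(inner, function(k) {
    i <- match(k, ks)
    num <- abs(mu[i + 1] - 2 * mu[i] + mu[i - 1])
    if (is.na(sds[i]) || sds[i] == 0) return(NA_real_)
    num / sds[i]
  }, numeric(1))
  names(delta) <- inner
  delta
}

# generate all permutations of 1..n (n small)
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      i <- i + 1L
      out[[i]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Align admixture runs affected by label switching and average them
#'
#' Columns of every run are matched to the first run's columns by maximising
#' the total column-wise correlation over all assignments (exhaustive search
#' for up to 8 groups, Hungarian assignment beyond). The element-wise mean of
#' the aligned runs is returned with rows renormalised to sum to 1.
#'
#' @param runs List of membership matrices (same samples in the same order,
#'   same number of groups; rows sum to 1).
#' @return Averaged membership matrix.
#' @export
align_structure_runs <- function(runs) {
  stopifnot(length(runs) >= 1)
  runs <- lapply(runs, as.matrix)
  k <- ncol(runs[[1]])
  n <- nrow(runs[[1]])
  if (any(vapply(runs, ncol, 0L) != k)) {
    stop("all runs must have the same number of groups")
  }
  if (any(vapply(runs, nrow, 0L) != n)) {
    stop("all runs must cover the same samples")
  }
  ref <- runs[[1]]
  aligned <- lapply(runs, function(run) {
    cc <- suppressWarnings(stats::cor(ref, run))
    cc[is.na(cc)] <- 0
    perm <- if (k <= 8) {
      perms <- all_permutations(k)
      scores <- vapply(perms, function(p) {
        sum(cc[cbind(seq_len(k), p)])
      }, numeric(1))
      perms[[which.max(scores)]]
    } else {
      as.integer(clue::solve_LSAP(cc - min(cc) + 1, maximum = TRUE))
    }
    run[, perm, drop = FALSE]
  })
  avg <- Reduce(`+`, aligned) / length(aligned)
  avg <- avg / rowSums(avg)
  dimnames(avg) <- dimnames(ref)
  avg
}

#' Realised relationship (kinship) matrices, optionally leave-one-chromosome-out
#'
#' Builds `K = MM^T` from the column-centred dosage matrix (missing dosages
#' mean-imputed per marker, no per-marker variance scaling), scaled so that
#' the mean diagonal equals 1. With `loco = TRUE` a separate kinship is
#' computed for every chromosome from all markers *not* on that chromosome,
#' which avoids a tested marker contaminating its own covariance correction.
#'
#' @param g A [geno_matrix()].
#' @param loco Compute leave-one-chromosome-out matrices as well?
#' @return A `kinship_set`: list with `global` (n x n), `per_chromosome`
#'   (named list, present when `loco`) and `samples`.
#' @export
compute_kinship <- function(g, loco = FALSE) {
  d <- impute_column_means(g$dosage)
  if (nrow(d) < 2) stop("kinship requires at least 2 samples")
  build <- function(cols) {
    m <- scale(d[, cols, drop = FALSE], center = TRUE, scale = FALSE)
    k <- tcrossprod(m)
    md <- mean(diag(k))
    if (md <= 0) stop("degenerate kinship: zero mean diagonal")
    k / md
  }
  chroms <- unique(g$info$chrom)
  per_chr <- NULL
  if (loco) {
    if (length(chroms) < 2) stop("LOCO requires >= 2 chromosomes")
    per_chr <- lapply(chroms, function(ch) build(g$info$chrom != ch))
    names(per_chr) <- chroms
  }
  structure(list(global = build(rep(TRUE, ncol(d))),
                 per_chromosome = per_chr,
                 samples = rownames(d)),
            class = "kinship_set")
}

#' Randomly subsample markers (e.g. for admixture software input)
#'
#' @param g A `geno_matrix`.
#' @param n Number of markers to keep.
#' @param seed Integer seed.
#' @return A `geno_matrix` with `n` markers (genomic order preserved).
#' @export
subsample_markers <- function(g, n, seed = 1) {
  m <- ncol(g$dosage)
  if (n >= m) return(g)
  keep <- sort(with_seed(seed, sample.int(m, n)))
  subset_markers(g, keep)
}

#' Export genotypes in STRUCTURE input format
#'
#' Writes one header line of marker ids followed by four rows per sample
#' (tetraploid), each carrying one binary allele (1 = alternate) per marker;
#' missing calls are coded -9. Allele order within a sample is arbitrary.
#'
#' @param g A `geno_matrix` with integer dosages.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_structure <- function(g, path) {
  d <- round(g$dosage)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(g$info$marker, collapse = " "), con)
  for (i in seq_len(nrow(d))) {
    alleles <- vapply(seq_len(4), function(copy) {
      vapply(d[i, ], function(x) {
        if (is.na(x)) return("-9")
        if (copy <= x) "1" else "0"
      }, "")
    }, character(ncol(d)))
    if (ncol(d) == 1) alleles <- matrix(alleles, nrow = 1)
    for (copy in seq_len(4)) {
      writeLines(paste(c(rownames(d)[i], alleles[, copy]), collapse = " "),
                 con)
    }
  }
  invisible(path)
}

#' Import posterior memberships from a STRUCTURE output file
#'
#' Parses the "Inferred ancestry of individuals" block (lines of the form
#' `idx label (miss) : p1 p2 ...`) and, when present, the estimated log
#' probability of the data.
#'
#' @param path STRUCTURE output file.
#' @return List with `membership` (samples x groups matrix, rows sum to 1)
#'   and `log_likelihood` (or `NA` if absent).
#' @export
import_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ll <- NA_real_
  ll_line <- grep("Estimated Ln Prob of Data", lines, value = TRUE)
  if (length(ll_line)) {
    ll <- as.numeric(sub(".*=\\s*", "", ll_line[1]))
  }
  start <- grep("Inferred ancestry of individuals", lines)
  if (!length(start)) stop("no 'Inferred ancestry of individuals' block in ",
                           path)
  block <- lines[(start[1] + 1):length(lines)]
  rows <- grep(":", block, value = TRUE)
  rows <- rows[grepl("^\\s*\\d+", rows)]
  if (!length(rows)) stop("empty ancestry block in ", path)
  parsed <- lapply(rows, function(l) {
    halves <- strsplit(l, ":", fixed = TRUE)[[1]]
    left <- strsplit(trimws(halves[1]), "\\s+")[[1]]
    probs <- as.numeric(strsplit(trimws(halves[2]), "\\s+")[[1]])
    list(label = left[2], probs = probs)
  })
  mem <- do.call(rbind, lapply(parsed, `[[`, "probs"))
  rownames(mem) <- vapply(parsed, `[[`, "", "label")
  colnames(mem) <- paste0("S", seq_len(ncol(mem)))
  mem <- mem / rowSums(mem)
  list(membership = mem, log_likelihood = ll)
}
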