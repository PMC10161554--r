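#' Fit the null mixed model for one population setting and chromosome
#'
#' Fits `y = X beta + u + e` with `Var(u) = sigma2_g K` and
#' `Var(e) = sigma2_e I` by REML, profiling the single variance ratio
#' `lambda = sigma2_g / sigma2_e` over the spectral decomposition of K. For
#' settings without kinship, K is the identity and the model collapses to
#' ordinary least squares. The decomposition and variance components are
#' reused for every marker test on the chromosome (the P3D approximation).
#'
#' @param y Named numeric phenotype vector (typically normalised BLUEs).
#' @param setting A [population_setting()].
#' @param K A `kinship_set` from [compute_kinship()], or `NULL` for identity.
#' @param chromosome Chromosome label selecting the leave-one-chromosome-out
#'   kinship; `NULL` uses the global matrix.
#' @return A `null_model_fit`: eigen rotation, variance components, rotated
#'   design, and the weighted null residual sum of squares.
#' @export
fit_null_model <- function(y, setting, K = NULL, chromosome = NULL) {
  samples <- names(y)
  if (is.null(samples)) stop("phenotype vector must be named by sample id")
  X <- setting_covariates(setting, samples)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[-seq_len(qrX$rank)]
    stop("singular covariate matrix; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  n <- length(y)

  use_K <- setting$uses_kinship && !is.null(K)
  if (use_K) {
    Km <- if (!is.null(chromosome) && !is.null(K$per_chromosome) &&
              chromosome %in% names(K$per_chromosome)) {
      K$per_chromosome[[chromosome]]
    } else K$global
    if (!is.null(K$samples)) {
      idx <- match(samples, K$samples)
      if (anyNA(idx)) stop("kinship matrix lacks some phenotyped samples")
      Km <- Km[idx, idx, drop = FALSE]
    }
    eig <- eigen(Km, symmetric = TRUE)
    U <- eig$vectors
    dvals <- pmax(eig$values, 0)
    ystar <- drop(crossprod(U, y))
    Xstar <- crossprod(U, X)
  } else {
    U <- NULL
    dvals <- rep(1, n)
    ystar <- unname(y)
    Xstar <- X
  }

  reml_crit <- function(log_lambda) {
    lambda <- exp(log_lambda)
    w <- lambda * dvals + 1
    sw <- sqrt(w)
    fit <- stats::lm.fit(Xstar / sw, ystar / sw)
    rss <- sum(fit$residuals^2)
    p <- fit$rank
    Rd <- abs(diag(qr.R(fit$qr)))
    (n - p) * log(rss) + sum(log(w)) + 2 * sum(log(Rd))
  }

  if (use_K) {
    opt <- stats::optimize(reml_crit, interval = c(-12, 12), tol = 1e-8)
    lambda <- exp(opt$minimum)
    # collapse to the boundary when the optimum sits on it
    if (opt$minimum <= -11.99) lambda <- 0
  } else {
    lambda <- 0
  }
  w <- lambda * dvals + 1
  sw <- sqrt(w)
  Xw <- Xstar / sw
  yw <- ystar / sw
  fit0 <- stats::lm.fit(Xw, yw)
  rss0 <- sum(fit0$residuals^2)
  rank0 <- fit0$rank
  sigma2_e <- rss0 / (n - rank0)
  structure(list(
    setting = setting$name, chromosome = chromosome,
    U = U, d = dvals, lambda = lambda,
    sigma2_g = lambda * sigma2_e, sigma2_e = sigma2_e,
    w = w, Xw = Xw, yw = yw, rss0 = rss0, rank0 = rank0, n = n,
    beta = fit0$coefficients
  ), class = "null_model_fit")
}

#' Score all markers under one genetic model and population setting
#'
#' Generalised-least-squares F-test of the encoded marker columns added to
#' the null fixed effects, with variance components fixed at their
#' per-chromosome null estimates (P3D). Missing dosages are mean-imputed per
#' marker before encoding. Markers whose encoding is constant or collinear
#' with the covariates are skipped with a reason.
#'
#' @param g A [geno_matrix()] aligned to the phenotyped samples.
#' @param y Named numeric phenotype vector.
#' @param model Genetic model name (see [genetic_models()]).
#' @param setting A [population_setting()].
#' @param K Optional `kinship_set` (used when the setting has kinship).
#' @param alpha Type-I error level for the FDR threshold.
#' @return A `gwas_result`: per-marker scores (`-log10 p`), F statistics and
#'   numerator df, plus the inflation factor and FDR threshold.
#' @export
score_markers <- function(g, y, model, setting, K = NULL, alpha = 0.05) {
  samples <- names(y)
  idx <- match(samples, rownames(g$dosage))
  if (anyNA(idx)) stop("genotype matrix lacks some phenotyped samples")
  d <- g$dosage[idx, , drop = FALSE]
  info <- g$info
  n <- length(y)
  m <- ncol(d)
  score <- Fstat <- pval <- rep(NA_real_, m)
  dfnum <- rep(NA_integer_, m)
  skipped <- rep(NA_character_, m)

  chroms <- unique(info$chrom)
  for (ch in chroms) {
    nf <- fit_null_model(y, setting, K = K,
                         chromosome = if (setting$uses_kinship) ch)
    cols <- which(info$chrom == ch)
    for (j in cols) {
      x <- d[, j]
      if (sum(!is.na(x)) < 3) {
        skipped[j] <- "too_few_samples"
        next
      }
      if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
      S <- encode_dosage(model, x)
      Sstar <- if (is.null(nf$U)) S else crossprod(nf$U, S)
      Sw <- Sstar / sqrt(nf$w)
      fit1 <- stats::lm.fit(cbind(nf$Xw, Sw), nf$yw)
      q_eff <- fit1$rank - nf$rank0
      if (q_eff < 1) {
        skipped[j] <- "constant_encoding"
        next
      }
      rss1 <- sum(fit1$residuals^2)
      df2 <- n - fit1$rank
      if (df2 < 1) {
        skipped[j] <- "insufficient_df"
        next
      }
      Fj <- ((nf$rss0 - rss1) / q_eff) / (rss1 / df2)
      pj <- stats::pf(Fj, q_eff, df2, lower.tail = FALSE)
      pj <- max(pj, 1e-300)
      Fstat[j] <- Fj
      pval[j] <- pj
      score[j] <- -log10(pj)
      dfnum[j] <- q_eff
    }
  }

  tab <- data.frame(marker = info$marker, chrom = info$chrom, pos = info$pos,
                    score = score, F = Fstat, df = dfnum, pvalue = pval,
                    skipped_reason = skipped, stringsAsFactors = FALSE)
  ok <- !is.na(pval)
  infl <- if (sum(ok) >= 10) inflation_factor(score[ok]) else NA_real_
  fdr <- fdr_score_threshold(pval[ok], alpha = alpha)
  structure(list(scores = tab, model = model, setting = setting$name,
                 inflation_factor = infl,
                 fdr_threshold = fdr$threshold,
                 significant = tab$marker[ok][fdr$significant_idx],
                 alpha = alpha, n = n),
            class = "gwas_result")
}

#' @export
print.gwas_result <- function(x, ...) {
  cat(sprintf("gwas_result: model %s, setting %s, %d markers (%d skipped)\n",
              x$model, x$setting, nrow(x$scores),
              sum(!is.na(x$scores$skipped_reason))))
  cat(sprintf("inflation factor %.3f; FDR threshold %s; %d significant\n",
              x$inflation_factor,
              ifelse(is.finite(x$fdr_threshold),
                     sprintf("%.3f", x$fdr_threshold), "none"),
              length(x$significant)))
  invisible(x)
}

#' Genomic inflation factor of marker scores
#'
#' Regression through the origin of the sorted observed scores on their
#' expected values under the global null, `-log10(i / (m + 1))`, pairing the
#' largest observed with the largest expected score. Values near 1 indicate
#' a well-calibrated test; larger values indicate inflation, typically from
#' unmodelled population structure.
#'
#' @param scores Numeric vector of `-log10 p` marker scores.
#' @return The inflation factor (regression slope).
#' @export
inflation_factor <- function(scores) {
  obs <- scores[!is.na(scores)]
  if (length(obs) < 10) stop("need at least 10 non-missing scores")
  if (stats::sd(obs) == 0 && all(obs == obs[1])) {
    stop("all scores equal; inflation factor undefined")
  }
  m <- length(obs)
  expected <- -log10(seq_len(m) / (m + 1))  # decreasing
  obs <- sort(obs, decreasing = TRUE)
  sum(obs * expected) / sum(expected^2)
}

#' Benjamini-Hochberg significance threshold on the score scale
#'
#' @param pvalues Numeric p-values in (0, 1].
#' @param alpha FDR level.
#' @return List with `threshold` (`-log10` of the largest significant
#'   p-value, `Inf` when nothing is significant), `significant_idx` (indices
#'   into `pvalues`) and `n_significant`.
#' @export
fdr_score_threshold <- function(pvalues, alpha = 0.05) {
  m <- length(pvalues)
  if (m == 0) {
    return(list(threshold = Inf, significant_idx = integer(0),
                n_significant = 0L))
  }
  ord <- order(pvalues)
  ps <- pvalues[ord]
  ok <- which(ps <= seq_len(m) * alpha / m)
  if (!length(ok)) {
    return(list(threshold = Inf, significant_idx = integer(0),
                n_significant = 0L))
  }
  k <- max(ok)
  sig <- which(pvalues <= ps[k])
  list(threshold = -log10(ps[k]), significant_idx = sig,
       n_significant = length(sig))
}

#' Select the population setting from mean inflation factors
#'
#' Among settings whose mean inflation factor (averaged over all genetic
#' models) exceeds 1, the one closest to 1 is chosen. If no setting exceeds
#' 1, the setting closest to 1 is returned with a flag.
#'
#' @param mean_inflation Named numeric vector of per-setting mean inflation
#'   factors.
#' @return List with `setting`, `mean_inflation` and `below_one` flag.
#' @export
select_population_setting <- function(mean_inflation) {
  if (!length(mean_inflation)) stop("no inflation factors supplied")
  above <- mean_inflation[mean_inflation > 1]
  if (length(above)) {
    best <- names(above)[which.min(above)]
    list(setting = best, mean_inflation = unname(above[which.min(above)]),
         below_one = FALSE)
  } else {
    i <- which.min(abs(mean_inflation - 1))
    list(setting = names(mean_inflation)[i],
         mean_inflation = unname(mean_inflation[i]), below_one = TRUE)
  }
}

#' High-scoring markers
#'
#' Markers whose score strictly exceeds `min_score` (the default 4
#' corresponds to an unadjusted p-value below 1e-4).
#'
#' @param scores Named numeric vector of marker scores, or a `gwas_result`.
#' @param min_score Score threshold (strict).
#' @return Character vector of marker ids.
#' @export
select_high_scoring <- function(scores, min_score = 4) {
  if (inherits(scores, "gwas_result")) {
    tab <- scores$scores
    scores <- stats::setNames(tab$score, tab$marker)
  }
  names(scores)[!is.na(scores) & scores > min_score]
}

#' Correlation matrix between GWAS score vectors
#'
#' Pearson correlations between the score vectors of multiple GWAS runs
#' (pairwise over markers scored in both), with an average-linkage
#' hierarchical clustering on `1 - r` providing a display order.
#'
#' @param results List of `gwas_result` objects sharing a marker set.
#' @return List with `correlation` (labelled matrix) and `order` (display
#'   order from the dendrogram).
#' @export
score_correlation_matrix <- function(results) {
  if (length(results) < 2) stop("need at least 2 result sets")
  markers <- results[[1]]$scores$marker
  mat <- vapply(results, function(r) {
    r$scores$score[match(markers, r$scores$marker)]
  }, numeric(length(markers)))
  colnames(mat) <- vapply(results, function(r) {
    paste(r$setting, r$model, sep = "|")
  }, "")
  cc <- stats::cor(mat, use = "pairwise.complete.obs")
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  list(correlation = cc, order = hc$order, hclust = hc)
}

#' Run the full genetic-model x population-setting GWAS grid
#'
#' @param g A [geno_matrix()].
#' @param y Named numeric phenotype vector.
#' @param settings Named list of [population_setting()] objects (e.g. from
#'   [standard_settings()]).
#' @param models Genetic model names (default: all eight).
#' @param K Optional `kinship_set`.
#' @param alpha FDR level.
#' @return List of `gwas_result` objects named `setting|model`.
#' @export
run_gwas_grid <- function(g, y, settings, models = genetic_models(),
                          K = NULL, alpha = 0.05) {
  out <- list()
  for (sname in names(settings)) {
    for (mod in models) {
      out[[paste(sname, mod, sep = "|")]] <-
        score_markers(g, y, mod, settings[[sname]], K = K, alpha = alpha)
    }
  }
  out
}
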