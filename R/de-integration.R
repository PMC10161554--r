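#' Filter lowly expressed genes
#'
#' Removes genes for which the number of samples with a read count below
#' `min_count` reaches `max_low_samples + 1` (i.e. keeps genes with at most
#' `max_low_samples` low-count samples).
#'
#' @param counts Genes x samples matrix of non-negative integer counts.
#' @param min_count Count below which a sample is "low" for a gene.
#' @param max_low_samples Maximum tolerated number of low-count samples.
#' @return Filtered count matrix.
#' @export
filter_low_expression <- function(counts, min_count = 5,
                                  max_low_samples = 4) {
  counts <- as.matrix(counts)
  n_low <- rowSums(counts < min_count)
  counts[n_low <= max_low_samples, , drop = FALSE]
}

#' Split significant DE genes into up- and down-regulated sets
#'
#' Significance is a strictly smaller adjusted p-value than `alpha`; the
#' direction is the sign of the log2 fold change. Significant genes with a
#' zero fold change are reported separately as ambiguous.
#'
#' @param de Data frame with columns `gene_id`, `log2_fold_change`,
#'   `adjusted_p` (the layout of [simple_de_test()] output).
#' @param alpha Significance level on the adjusted p-value.
#' @return List with `up`, `down` and `ambiguous` gene id vectors.
#' @export
significant_de <- function(de, alpha = 0.05) {
  sig <- !is.na(de$adjusted_p) & de$adjusted_p < alpha
  list(up = de$gene_id[sig & de$log2_fold_change > 0],
       down = de$gene_id[sig & de$log2_fold_change < 0],
       ambiguous = de$gene_id[sig & de$log2_fold_change == 0])
}

# median-of-ratios size factors (falls back to relative library size when no
# gene is expressed everywhere)
size_factors <- function(counts) {
  log_geo <- rowMeans(log(counts))
  ok <- is.finite(log_geo)
  if (any(ok)) {
    sf <- apply(counts, 2, function(s) {
      exp(stats::median(log(s[ok]) - log_geo[ok]))
    })
  } else {
    ls <- colSums(counts)
    sf <- ls / exp(mean(log(ls)))
  }
  sf
}

#' Convenience differential-expression test between two groups
#'
#' A plumbing-level two-group test: counts are normalised by
#' median-of-ratios size factors, log2(x + 1)-transformed, and compared with
#' a per-gene Welch t-test; p-values are Benjamini-Hochberg adjusted. The
#' log2 fold change is the difference of group means on the transformed
#' scale (high minus low). Genes with zero variance in both groups get
#' p = 1. This is a simple screen, not a replacement for a count-model DE
#' fit.
#'
#' @param counts Genes x samples matrix of counts.
#' @param groups Named character vector (`"low"`/`"high"`) or factor mapping
#'   sample to group.
#' @param coords Optional data frame with `gene_id`, `chromosome`, `start`,
#'   `end` to carry through.
#' @return Data frame with `gene_id`, `log2_fold_change`, `p_value`,
#'   `adjusted_p` (plus coordinates when supplied).
#' @export
simple_de_test <- function(counts, groups, coords = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(names(groups))) groups <- groups[colnames(counts)]
  groups <- as.character(groups)
  lo <- which(groups == "low")
  hi <- which(groups == "high")
  if (length(lo) < 2 || length(hi) < 2) {
    stop("need at least 2 samples per group")
  }
  sf <- size_factors(counts)
  x <- log2(sweep(counts, 2, sf, "/") + 1)
  res <- t(apply(x, 1, function(g) {
    a <- g[hi]; b <- g[lo]
    lfc <- mean(a) - mean(b)
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      return(c(lfc = lfc, p = 1))
    }
    p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
    c(lfc = lfc, p = p)
  }))
  data.frame(
    gene_id = rownames(counts) %||% paste0("gene_", seq_len(nrow(counts))),
    chromosome = if (!is.null(coords)) coords$chromosome else NA,
    start = if (!is.null(coords)) coords$start else NA,
    end = if (!is.null(coords)) coords$end else NA,
    log2_fold_change = res[, "lfc"],
    p_value = res[, "p"],
    adjusted_p = stats::p.adjust(res[, "p"], method = "BH"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Functional-class-scoring enrichment (prototype two-sample t-test)
#'
#' For each gene set, the mean gene score of the set is contrasted with the
#' mean score of the background (all scored genes outside the set) using a
#' prototype two-sample t-statistic
#' `t = (mean_set - mean_bg) / sqrt(var_set/m + var_bg/n_bg)` with
#' Welch-Satterthwaite degrees of freedom, which is calibrated (uniform
#' p-values) for sets drawn at random from the background. With
#' `virtual_set = TRUE` the background variance is instead divided by the
#' *set* size `m`, realising a comparison against a virtual random set of
#' the same size drawn from the background — a deliberately conservative
#' variant. One-sided (greater) p-values are Benjamini-Hochberg adjusted
#' across sets. Unscored genes in a set are ignored. Gene scores are
#' typically `-log10` adjusted DE p-values (see [de_gene_scores()]).
#'
#' @param gene_scores Named numeric vector of gene scores.
#' @param sets Named list of gene id vectors, or a data frame with columns
#'   `set_id`, `gene_id`.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @param virtual_set Use the same-size virtual-set denominator
#'   (`var_bg/m`) instead of the calibrated `var_bg/n_bg`.
#' @return Data frame with `set_id`, `set_size`, `t_statistic`, `p_value`,
#'   `adjusted_p`, `skipped_reason`.
#' @export
fcs_enrichment <- function(gene_scores, sets,
                           alternative = c("greater", "two.sided"),
                           virtual_set = FALSE) {
  alternative <- match.arg(alternative)
  if (is.data.frame(sets)) {
    sets <- split(as.character(sets$gene_id), sets$set_id)
  }
  all_genes <- names(gene_scores)
  rows <- lapply(names(sets), function(sid) {
    members <- intersect(sets[[sid]], all_genes)
    m <- length(members)
    if (m < 2) {
      return(data.frame(set_id = sid, set_size = m, t_statistic = NA_real_,
                        p_value = NA_real_, skipped_reason = "too_few_scored",
                        stringsAsFactors = FALSE))
    }
    s <- gene_scores[members]
    bg <- gene_scores[setdiff(all_genes, members)]
    vs <- stats::var(s)
    vb <- stats::var(bg)
    nb <- if (virtual_set) m else length(bg)
    se2 <- vs / m + vb / nb
    if (se2 <= 0) {
      tt <- if (mean(s) == mean(bg)) 0 else sign(mean(s) - mean(bg)) * Inf
      df <- m - 1
    } else {
      tt <- (mean(s) - mean(bg)) / sqrt(se2)
      df_den_b <- if (virtual_set) m - 1 else length(bg) - 1
      df <- se2^2 / ((vs / m)^2 / (m - 1) + (vb / nb)^2 / df_den_b)
    }
    p <- stats::pt(tt, df, lower.tail = FALSE)
    if (alternative == "two.sided") p <- 2 * min(p, 1 - p)
    data.frame(set_id = sid, set_size = m, t_statistic = tt, p_value = p,
               skipped_reason = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("set_id", "set_size", "t_statistic", "p_value", "adjusted_p",
          "skipped_reason")]
}

#' Gene scores for enrichment from a DE table
#'
#' `-log10` of the adjusted p-value, floored at 1e-300.
#'
#' @param de DE result data frame (see [simple_de_test()]).
#' @return Named numeric vector of gene scores.
#' @export
de_gene_scores <- function(de) {
  stats::setNames(-log10(pmax(de$adjusted_p, 1e-300)), de$gene_id)
}
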