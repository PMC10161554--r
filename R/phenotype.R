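#' Genotype BLUEs from replicate-structured bruising scores
#'
#' Fits the mixed model `score ~ genotype (fixed) + replicate nested in
#' genotype (random) + residual` by REML and returns the per-genotype
#' fixed-effect estimates (mu + G_i), the Best Linear Unbiased Estimates used
#' as the GWAS phenotype. When every genotype-replicate cell holds a single
#' observation the replicate effect is confounded with the residual and the
#' model reduces to ordinary least squares on genotype means.
#'
#' @param scores Data frame with columns `genotype`, `replicate`, `tuber`,
#'   `score` (bruising score on the 0--5 visual scale).
#' @return Data frame with columns `genotype` and `blue`.
#' @export
compute_blues <- function(scores) {
  stopifnot(all(c("genotype", "replicate", "score") %in% names(scores)))
  scores$genotype <- as.character(scores$genotype)
  bad <- is.na(scores$score)
  if (any(bad)) {
    dropped <- setdiff(unique(scores$genotype),
                       unique(scores$genotype[!bad]))
    if (length(dropped)) {
      warning("genotype(s) with all-missing scores excluded: ",
              paste(dropped, collapse = ", "))
    }
    scores <- scores[!bad, , drop = FALSE]
  }
  if (length(unique(scores$genotype)) < 2) {
    stop("BLUE estimation requires at least 2 genotypes")
  }
  scores$genotype <- factor(scores$genotype)
  cell <- interaction(scores$genotype, scores$replicate, drop = TRUE)
  if (nlevels(cell) < nrow(scores)) {
    fit <- suppressMessages(lme4::lmer(
      score ~ 0 + genotype + (1 | genotype:replicate),
      data = scores, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  check.conv.grad = "ignore",
                                  check.conv.hess = "ignore",
                                  calc.derivs = FALSE)))
    est <- lme4::fixef(fit)
  } else {
    est <- stats::coef(stats::lm(score ~ 0 + genotype, data = scores))
  }
  data.frame(genotype = sub("^genotype", "", names(est)),
             blue = unname(est), stringsAsFactors = FALSE)
}

#' Yeo-Johnson power transform
#'
#' @param x Numeric vector.
#' @param lambda Transform parameter.
#' @return Transformed vector.
#' @export
yeo_johnson <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  neg <- !is.na(x) & x < 0
  if (abs(lambda) > 1e-12) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else {
    out[pos] <- log1p(x[pos])
  }
  if (abs(lambda - 2) > 1e-12) {
    out[neg] <- -(((-x[neg] + 1)^(2 - lambda)) - 1) / (2 - lambda)
  } else {
    out[neg] <- -log1p(-x[neg])
  }
  out[is.na(x)] <- NA_real_
  out
}

yj_loglik <- function(x, lambda) {
  z <- yeo_johnson(x, lambda)
  s2 <- mean((z - mean(z))^2)
  if (s2 <= 0) return(-Inf)
  n <- length(x)
  -n / 2 * log(s2) +
    (lambda - 1) * sum(log1p(x[x >= 0])) +
    (1 - lambda) * sum(log1p(-x[x < 0]))
}

#' Standardised Yeo-Johnson normalisation
#'
#' Selects the Yeo-Johnson parameter maximising the Gaussian profile
#' log-likelihood over `[-2, 2]` (bounded scalar optimisation; near-ties
#' resolved towards the identity lambda = 1), applies the transform, and
#' centres/scales the result to mean 0 and standard deviation 1.
#'
#' @param values Numeric vector (>= 3 finite values, non-constant).
#' @return List with `normalized` (standardised values), `lambda`, `mean`
#'   and `sd` of the transformed values.
#' @export
yeo_johnson_standardize <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) < 3) stop("need at least 3 finite values")
  if (stats::sd(x) == 0) stop("input is constant; cannot normalise")
  opt <- stats::optimize(function(l) yj_loglik(x, l), interval = c(-2, 2),
                         maximum = TRUE, tol = 1e-6)
  lambda <- opt$maximum
  if (abs(yj_loglik(x, 1) - opt$objective) < 1e-9) lambda <- 1
  z <- yeo_johnson(values, lambda)
  mu <- mean(z, na.rm = TRUE)
  sg <- stats::sd(z, na.rm = TRUE)
  list(normalized = (z - mu) / sg, lambda = lambda, mean = mu, sd = sg)
}

#' Classify genotypes into low/high bruising groups
#'
#' Genotypes with a mean bruising score of `low_max` or less form the low
#' group, those with `high_min` or more the high group (both boundaries
#' inclusive); the remainder are excluded from the differential-expression
#' contrast.
#'
#' @param mean_scores Named numeric vector of per-genotype mean scores (mean
#'   over a replicate's tubers).
#' @param low_max Upper bound of the low group.
#' @param high_min Lower bound of the high group.
#' @return Named character vector with values `"low"`, `"high"` or
#'   `"excluded"`.
#' @export
classify_bruising_groups <- function(mean_scores, low_max = 1, high_min = 2) {
  out <- rep("excluded", length(mean_scores))
  out[mean_scores <= low_max] <- "low"
  out[mean_scores >= high_min] <- "high"
  names(out) <- names(mean_scores)
  out
}
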