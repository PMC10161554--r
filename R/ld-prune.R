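#' Squared Pearson correlation between two dosage columns
#'
#' Computed over complete pairs only (indices where both columns are
#' non-missing). With fewer than two complete pairs, or zero variance in
#' either column over the complete pairs, the value is undefined and treated
#' as no linkage (r^2 = 0), so the candidate marker is retained during
#' pruning.
#'
#' @param x,y Numeric dosage columns of equal length.
#' @param undefined Value returned when r^2 is undefined (default 0; pass
#'   `NA` to see undefined pairs explicitly).
#' @return Squared correlation in `[0, 1]`, or `undefined`.
#' @export
pairwise_r2 <- function(x, y, undefined = 0) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(undefined)
  xs <- x[ok]; ys <- y[ok]
  if (stats::var(xs) == 0 || stats::var(ys) == 0) return(undefined)
  stats::cor(xs, ys)^2
}

#' Prune one chromosome by windowed linkage disequilibrium
#'
#' Bidirectional windowed pruning: a random starting variant (chosen with
#' `seed`) founds the retained set S. Variants to the right of the start are
#' scanned in position order; a candidate j is dropped if some retained
#' variant k lies within `window_bp` of j (inclusive) with r^2(j, k) above
#' `r2_threshold`, otherwise j joins S. When the chromosome end is reached
#' the scan resumes from the variant immediately left of the start and
#' proceeds towards the chromosome beginning under the same rule, against the
#' same growing set S.
#'
#' @param g A [geno_matrix()] restricted to a single chromosome.
#' @param window_bp Window size in base pairs (inclusive bound).
#' @param r2_threshold r^2 above which a nearby retained variant blocks the
#'   candidate.
#' @param seed Integer seed fixing the starting variant.
#' @param drop_undefined If `TRUE`, an undefined r^2 counts as blocking
#'   (default `FALSE`: undefined means no linkage).
#' @return A `prune_result`: list with `retained` (marker ids, genomic
#'   order), `dropped` (data frame of dropped marker, blocking marker, r^2),
#'   `seed`, `window_bp`, `r2_threshold`.
#' @export
prune_chromosome <- function(g, window_bp = 100000, r2_threshold = 0.5,
                             seed = 1, drop_undefined = FALSE) {
  m <- ncol(g$dosage)
  res <- list(retained = character(0),
              dropped = data.frame(marker = character(0),
                                   blocked_by = character(0),
                                   r2 = numeric(0),
                                   stringsAsFactors = FALSE),
              seed = seed, window_bp = window_bp,
              r2_threshold = r2_threshold)
  class(res) <- "prune_result"
  if (m == 0) return(res)
  if (length(unique(g$info$chrom)) > 1) {
    stop("prune_chromosome expects a single chromosome; see prune_genome()")
  }
  pos <- g$info$pos
  ids <- g$info$marker
  d <- g$dosage
  undef <- if (drop_undefined) Inf else 0

  start <- with_seed(seed, sample.int(m, 1))
  keep <- logical(m)
  keep[start] <- TRUE
  blocked_by <- rep(NA_integer_, m)
  block_r2 <- rep(NA_real_, m)

  consider <- function(j, keep) {
    in_win <- which(keep & abs(pos - pos[j]) <= window_bp)
    for (k in in_win) {
      r2 <- pairwise_r2(d[, j], d[, k], undefined = undef)
      if (r2 > r2_threshold) {
        return(list(blocked = TRUE, k = k, r2 = r2))
      }
    }
    list(blocked = FALSE)
  }

  scan <- c(if (start < m) (start + 1L):m, if (start > 1) (start - 1L):1)
  for (j in scan) {
    v <- consider(j, keep)
    if (v$blocked) {
      blocked_by[j] <- v$k
      block_r2[j] <- v$r2
    } else {
      keep[j] <- TRUE
    }
  }
  res$retained <- ids[keep]
  dropped <- which(!keep)
  res$dropped <- data.frame(marker = ids[dropped],
                            blocked_by = ids[blocked_by[dropped]],
                            r2 = block_r2[dropped],
                            stringsAsFactors = FALSE)
  res
}

#' Prune a whole genome by windowed linkage disequilibrium
#'
#' Applies [prune_chromosome()] independently to every chromosome; each
#' chromosome's starting variant is drawn from a seed derived
#' deterministically from `seed` and the chromosome's rank, so results are
#' reproducible and chromosomes do not influence one another.
#'
#' @inheritParams prune_chromosome
#' @param g A [geno_matrix()].
#' @return A `prune_result` covering all chromosomes.
#' @export
prune_genome <- function(g, window_bp = 100000, r2_threshold = 0.5, seed = 1,
                         drop_undefined = FALSE) {
  chroms <- unique(g$info$chrom)
  parts <- lapply(seq_along(chroms), function(i) {
    gc <- subset_markers(g, which(g$info$chrom == chroms[i]))
    prune_chromosome(gc, window_bp = window_bp, r2_threshold = r2_threshold,
                     seed = stage_seed(seed, i), drop_undefined = drop_undefined)
  })
  res <- list(
    retained = unlist(lapply(parts, `[[`, "retained"), use.names = FALSE),
    dropped = do.call(rbind, lapply(parts, `[[`, "dropped")),
    seed = seed, window_bp = window_bp, r2_threshold = r2_threshold
  )
  if (is.null(res$dropped)) {
    res$dropped <- data.frame(marker = character(0), blocked_by = character(0),
                              r2 = numeric(0), stringsAsFactors = FALSE)
  }
  class(res) <- "prune_result"
  res
}

#' @export
print.prune_result <- function(x, ...) {
  cat(sprintf("prune_result: %d retained, %d dropped (window %g bp, r2 > %g, seed %d)\n",
              length(x$retained), nrow(x$dropped), x$window_bp,
              x$r2_threshold, x$seed))
  invisible(x)
}

#' Apply a prune result to a genotype matrix
#' @param g A `geno_matrix`.
#' @param prune A `prune_result`.
#' @return The `geno_matrix` restricted to retained markers.
#' @export
apply_prune <- function(g, prune) {
  subset_markers(g, which(g$info$marker %in% prune$retained))
}
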