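# Shared fixture builders and independent oracle implementations.

# small geno_matrix from a dosage matrix (samples x markers)
toy_geno <- function(dosage, chrom = NULL, pos = NULL, ref = "A", alt = "T",
                     qual = NA_real_, depths = NULL,
                     dosage_kind = "most_probable") {
  m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  if (m > 0 && is.null(colnames(dosage))) {
    colnames(dosage) <- paste0("m", seq_len(m))
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("s", seq_len(nrow(dosage)))
  }
  info <- data.frame(marker = if (is.null(colnames(dosage))) character(0) else colnames(dosage),
                     chrom = chrom, pos = pos,
                     ref = rep_len(ref, m), alt = rep_len(alt, m),
                     qual = rep_len(qual, m), stringsAsFactors = FALSE)
  geno_matrix(dosage, info, depths = depths, dosage_kind = dosage_kind)
}

# write a minimal tetraploid VCF
write_toy_vcf <- function(path, records, samples) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(hdr, records), path)
}

vcf_record <- function(chrom, pos, id, ref, alt, qual, gts, dps = NULL) {
  fmt <- if (is.null(dps)) "GT" else "GT:DP"
  cells <- if (is.null(dps)) gts else paste(gts, dps, sep = ":")
  paste(c(chrom, pos, id, ref, alt, qual, ".", ".", fmt, cells),
        collapse = "\t")
}

# Independent brute-force implementation of the bidirectional windowed LD
# pruning procedure: literal translation of the published description, no
# shared code with prune_chromosome().
brute_force_prune <- function(dosage, pos, window_bp, r2_threshold, start) {
  m <- length(pos)
  r2 <- function(a, b) {
    ok <- !is.na(dosage[, a]) & !is.na(dosage[, b])
    if (sum(ok) < 2) return(0)
    x <- dosage[ok, a]; y <- dosage[ok, b]
    if (length(unique(x)) < 2 || length(unique(y)) < 2) return(0)
    suppressWarnings(stats::cor(x, y))^2
  }
  S <- start
  right <- if (start < m) (start + 1):m else integer(0)
  left <- if (start > 1) (start - 1):1 else integer(0)
  for (j in c(right, left)) {
    blocked <- FALSE
    for (k in S) {
      if (abs(pos[j] - pos[k]) <= window_bp && r2(j, k) > r2_threshold) {
        blocked <- TRUE
        break
      }
    }
    if (!blocked) S <- c(S, j)
  }
  sort(S)
}

# OLS F-test oracle for the naive GWAS setting: plain lm + anova.
ols_score_oracle <- function(y, X_extra, S) {
  df <- data.frame(y = y)
  fit0 <- stats::lm(y ~ 1, data = df)
  fit1 <- stats::lm(y ~ 1 + S)
  a <- stats::anova(fit0, fit1)
  p <- a[2, "Pr(>F)"]
  -log10(max(p, 1e-300))
}

# all-pairs brute-force colocalization oracle
brute_force_coloc <- function(data, window_bp) {
  out <- list()
  for (ch in unique(data$chromosome)) {
    dd <- data[data$chromosome == ch, ]
    mk <- dd[dd$layer == "marker", ]
    gn <- dd[dd$layer == "de_gene", ]
    if (!nrow(mk) || !nrow(gn)) next
    # adjacency over all rows; expand components by repeated sweeps
    items <- rbind(data.frame(pos = mk$position, label = mk$label, kind = "m"),
                   data.frame(pos = gn$position, label = gn$label, kind = "g"))
    n <- nrow(items)
    grp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          linked <- items$kind[i] != items$kind[j] &&
            abs(items$pos[i] - items$pos[j]) <= window_bp
          if (linked && grp[i] != grp[j]) {
            grp[grp == grp[j]] <- grp[i]
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    for (gid in unique(grp)) {
      mem <- items[grp == gid, ]
      if (!any(mem$kind == "m") || !any(mem$kind == "g")) next
      out[[length(out) + 1]] <- data.frame(
        chromosome = ch,
        start = floor(min(mem$pos) / 1e5) * 1e5,
        end = ceiling(max(mem$pos) / 1e5) * 1e5,
        n_markers = sum(mem$kind == "m"),
        n_genes = sum(mem$kind == "g"))
    }
  }
  if (!length(out)) {
    return(data.frame(chromosome = character(0), start = numeric(0),
                      end = numeric(0), n_markers = integer(0),
                      n_genes = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$chromosome, res$start), , drop = FALSE]
}
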