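#' Read tetraploid genotypes from a VCF file
#'
#' Parses a VCF with tetraploid `GT` calls (four alleles per call) or a
#' numeric dosage `FORMAT` field, and returns the alternate-allele dosage
#' matrix. Multi-allelic records are kept but flagged through their `alt`
#' metadata so [select_biallelic_het_snps()] can drop them; partially missing
#' calls become missing dosages.
#'
#' @param path Path to a VCF 4.x file.
#' @param dosage_kind `"most_probable"` to derive integer dosages from `GT`,
#'   `"posterior_mean"` to read real-valued dosages from `dosage_field`.
#' @param dosage_field FORMAT field holding numeric dosages (default `"DS"`),
#'   used only for `posterior_mean`.
#' @return A [geno_matrix()] with `qual` and per-sample depths (`DP`)
#'   attached when present.
#' @export
read_vcf_dosages <- function(path, dosage_kind = c("most_probable",
                                                   "posterior_mean"),
                             dosage_field = "DS") {
  dosage_kind <- match.arg(dosage_kind)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_mark <- nrow(fix)
  marker <- fix[, "ID"]
  no_id <- is.na(marker) | marker == "."
  marker[no_id] <- paste0(fix[no_id, "CHROM"], "_", fix[no_id, "POS"])
  marker <- make.unique(marker)
  info <- data.frame(
    marker = marker,
    chrom = fix[, "CHROM"],
    pos = as.numeric(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    stringsAsFactors = FALSE
  )
  if (dosage_kind == "most_probable") {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    d <- matrix(NA_real_, nrow = n_mark, ncol = ncol(gt))
    for (j in seq_len(ncol(gt))) {
      alleles <- strsplit(gt[, j], "[/|]")
      d[, j] <- vapply(alleles, function(a) {
        if (length(a) == 0 || all(a == ".") || anyNA(a)) return(NA_real_)
        if (length(a) != 4) {
          stop("ploidy error: expected 4 alleles per GT call, found ",
               length(a), call. = FALSE)
        }
        if (any(a == ".")) return(NA_real_)
        sum(a != "0")
      }, numeric(1))
    }
    colnames(d) <- colnames(gt)
  } else {
    ds <- vcfR::extract.gt(vcf, element = dosage_field, as.numeric = TRUE)
    if (all(is.na(ds))) {
      stop("dosage field '", dosage_field, "' absent or empty in VCF")
    }
    d <- ds
  }
  dp <- tryCatch(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  dosage <- t(d)
  rownames(dosage) <- colnames(d)
  colnames(dosage) <- info$marker
  depths <- if (!is.null(dp)) {
    dpt <- t(dp)
    dimnames(dpt) <- dimnames(dosage)
    dpt
  }
  geno_matrix(dosage, info, depths = depths, dosage_kind = dosage_kind)
}

#' QualByDepth (QD) score of a marker
#'
#' QD is the variant quality divided by the summed read depth over
#' non-homozygous samples (dosage in 1--3). With no heterozygous sample or
#' zero total depth the score is undefined (`NA`), and the marker fails the
#' QD filter with reason `"qd_undefined"`.
#'
#' @param qual Variant quality (Phred-like, >= 0).
#' @param dosages Per-sample dosage column for the marker.
#' @param depths Per-sample read depths for the marker.
#' @return QD value, or `NA` if undefined.
#' @export
compute_qd <- function(qual, dosages, depths) {
  if (is.na(qual)) return(NA_real_)
  het <- !is.na(dosages) & dosages >= 1 & dosages <= 3
  tot <- sum(depths[het], na.rm = TRUE)
  if (!any(het) || !is.finite(tot) || tot <= 0) return(NA_real_)
  qual / tot
}

#' Retain only heterozygous biallelic SNPs
#'
#' Keeps markers that are single-nucleotide substitutions with a single ALT
#' allele and at least one heterozygous sample (dosage in 1--3). Indels and
#' multi-allelic records are dropped, never decomposed. Marker order is
#' preserved.
#'
#' @param g A [geno_matrix()] carrying `ref`/`alt` metadata.
#' @return Filtered `geno_matrix` (possibly with zero markers).
#' @export
select_biallelic_het_snps <- function(g) {
  info <- g$info
  ref <- info$ref %||% rep(NA_character_, nrow(info))
  alt <- info$alt %||% rep(NA_character_, nrow(info))
  is_snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1 & nchar(alt) == 1 & !grepl(",", alt, fixed = TRUE)
  d <- g$dosage
  has_het <- apply(d, 2, function(x) any(!is.na(x) & x >= 1 & x <= 3))
  subset_markers(g, which(is_snp & has_het))
}

#' Apply the variant-level quality filters
#'
#' Three sequential rules: (i) per-marker missing fraction must not exceed
#' `max_missing` (exactly 10% missing passes by default; set
#' `strict_missing = TRUE` to fail it), (ii) QD >= `min_qd` (markers with an
#' undefined QD fail), and (iii) minor allele frequency strictly greater than
#' `min_maf`, with MAF = min(f, 1 - f) and f the mean dosage / 4 over
#' non-missing samples. The QD rule is applied only when quality and depth
#' metadata are available. A marker failing several rules is counted against
#' the first rule, so the report counts sum to the number removed.
#'
#' @param g A `geno_matrix`, typically from [select_biallelic_het_snps()].
#' @param max_missing Maximum tolerated per-marker missing fraction.
#' @param min_qd Minimum QualByDepth score.
#' @param min_maf Minor-allele-frequency threshold (strict).
#' @param strict_missing If `TRUE`, a missing fraction equal to `max_missing`
#'   also fails.
#' @return List with `geno` (filtered `geno_matrix`) and `report` (counts
#'   removed per rule).
#' @export
apply_variant_filters <- function(g, max_missing = 0.10, min_qd = 2,
                                  min_maf = 0.01, strict_missing = FALSE) {
  d <- g$dosage
  m <- ncol(d)
  report <- list(n_input = m, missing = 0L, qd = 0L, maf = 0L, n_retained = 0L)
  if (m == 0) {
    return(list(geno = g, report = report))
  }
  miss_frac <- colMeans(is.na(d))
  fail_miss <- if (strict_missing) miss_frac >= max_missing else
    miss_frac > max_missing

  has_qd_meta <- !is.null(g$depths) && !is.null(g$info$qual) &&
    any(!is.na(g$info$qual))
  fail_qd <- rep(FALSE, m)
  if (has_qd_meta) {
    qd <- vapply(seq_len(m), function(j) {
      compute_qd(g$info$qual[j], d[, j], g$depths[, j])
    }, numeric(1))
    fail_qd <- is.na(qd) | qd < min_qd
  }

  f <- colMeans(d, na.rm = TRUE) / 4
  maf <- pmin(f, 1 - f)
  fail_maf <- !(maf > min_maf) | is.na(maf)

  first_fail <- rep(NA_character_, m)
  first_fail[fail_maf] <- "maf"
  first_fail[fail_qd] <- "qd"
  first_fail[fail_miss] <- "missing"
  keep <- is.na(first_fail)
  report$missing <- sum(first_fail == "missing", na.rm = TRUE)
  report$qd <- sum(first_fail == "qd", na.rm = TRUE)
  report$maf <- sum(first_fail == "maf", na.rm = TRUE)
  report$n_retained <- sum(keep)
  list(geno = subset_markers(g, which(keep)), report = report)
}

#' Remove samples with excessive missingness
#'
#' Drops samples whose fraction of missing dosages is strictly greater than
#' `max_missing` (a sample missing exactly 10% of markers is kept).
#'
#' @param g A `geno_matrix`.
#' @param max_missing Missing-fraction threshold.
#' @return Filtered `geno_matrix`.
#' @export
apply_sample_filter <- function(g, max_missing = 0.10) {
  miss <- rowMeans(is.na(g$dosage))
  keep <- miss <= max_missing
  if (!any(keep)) stop("no samples remain after the missingness filter")
  subset_samples(g, which(keep))
}
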