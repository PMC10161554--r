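#' Allele-dosage genotype matrix for autotetraploids
#'
#' The central genotype container: a samples x markers matrix of alternate
#' allele dosages (0--4, `NA` for missing) together with per-marker metadata.
#' Markers are kept sorted by (chromosome, position).
#'
#' @param dosage Numeric matrix, samples in rows, markers in columns. Row
#'   names are sample ids, column names marker ids. Values in `[0, 4]` or
#'   `NA`.
#' @param info Data frame with one row per marker: columns `marker`, `chrom`,
#'   `pos` (1-based bp), and optionally `ref`, `alt` (comma-separated if
#'   multi-allelic) and `qual`.
#' @param depths Optional matrix of per-sample read depths, same shape as
#'   `dosage`.
#' @param dosage_kind Either `"most_probable"` (integer dosages) or
#'   `"posterior_mean"` (real-valued dosages).
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, info, depths = NULL,
                        dosage_kind = c("most_probable", "posterior_mean")) {
  dosage_kind <- match.arg(dosage_kind)
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("sample_", seq_len(nrow(dosage)))
  }
  stopifnot(is.data.frame(info), nrow(info) == ncol(dosage))
  need <- c("marker", "chrom", "pos")
  missing_cols <- setdiff(need, names(info))
  if (length(missing_cols)) {
    stop("marker info lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  info$marker <- as.character(info$marker)
  info$chrom <- as.character(info$chrom)
  info$pos <- as.numeric(info$pos)
  if (any(info$pos < 1, na.rm = TRUE)) stop("marker positions must be >= 1")
  if (is.null(colnames(dosage))) colnames(dosage) <- info$marker
  rng <- suppressWarnings(range(dosage, na.rm = TRUE))
  if (!all(is.finite(rng))) rng <- c(0, 0)
  if (rng[1] < 0 || rng[2] > 4) stop("dosages must lie in [0, 4]")
  if (dosage_kind == "most_probable" &&
      any(abs(dosage - round(dosage)) > 1e-8, na.rm = TRUE)) {
    stop("most_probable dosages must be integers")
  }
  if (!is.null(depths)) {
    depths <- as.matrix(depths)
    stopifnot(all(dim(depths) == dim(dosage)))
  }
  ord <- order(info$chrom, info$pos)
  info <- info[ord, , drop = FALSE]
  rownames(info) <- NULL
  dosage <- dosage[, ord, drop = FALSE]
  if (!is.null(depths)) depths <- depths[, ord, drop = FALSE]
  colnames(dosage) <- info$marker
  structure(
    list(dosage = dosage, info = info, depths = depths,
         dosage_kind = dosage_kind),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d markers (%s dosages)\n",
              nrow(x$dosage), ncol(x$dosage), x$dosage_kind))
  cat(sprintf("chromosomes: %s\n",
              paste(unique(x$info$chrom), collapse = ", ")))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("missing: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a geno_matrix by marker index or id
#' @param g A `geno_matrix`.
#' @param idx Integer or logical index into markers, or marker ids.
#' @return A `geno_matrix` with the selected markers.
#' @export
subset_markers <- function(g, idx) {
  if (is.character(idx)) idx <- match(idx, g$info$marker)
  geno_matrix(g$dosage[, idx, drop = FALSE], g$info[idx, , drop = FALSE],
              depths = if (!is.null(g$depths)) g$depths[, idx, drop = FALSE],
              dosage_kind = g$dosage_kind)
}

#' Subset a geno_matrix by sample index or id
#' @param g A `geno_matrix`.
#' @param idx Integer or logical index into samples, or sample ids.
#' @return A `geno_matrix` with the selected samples.
#' @export
subset_samples <- function(g, idx) {
  if (is.character(idx)) idx <- match(idx, rownames(g$dosage))
  geno_matrix(g$dosage[idx, , drop = FALSE], g$info,
              depths = if (!is.null(g$depths)) g$depths[idx, , drop = FALSE],
              dosage_kind = g$dosage_kind)
}

#' Write a geno_matrix in the dosage CSV dialect
#'
#' The dialect is: a header row of marker ids, three metadata rows
#' (`chrom`, `pos`, `ref_alt`), then one row per sample. Missing dosages are
#' written as empty cells.
#'
#' @param g A `geno_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dosage_csv <- function(g, path) {
  info <- g$info
  ref_alt <- if (!is.null(info$ref)) {
    paste0(info$ref, "/", info$alt %||% "")
  } else rep("", nrow(info))
  hdr <- c("id", info$marker)
  rows <- list(
    c("chrom", info$chrom),
    c("pos", format(info$pos, scientific = FALSE, trim = TRUE)),
    c("ref_alt", ref_alt)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = ","), con)
  for (r in rows) writeLines(paste(r, collapse = ","), con)
  d <- g$dosage
  for (i in seq_len(nrow(d))) {
    vals <- ifelse(is.na(d[i, ]), "",
                   format(d[i, ], scientific = FALSE, trim = TRUE, digits = 15))
    writeLines(paste(c(rownames(d)[i], vals), collapse = ","), con)
  }
  invisible(path)
}

#' Read a geno_matrix from the dosage CSV dialect
#'
#' @param path CSV file written by [write_dosage_csv()] (or following the
#'   same layout).
#' @param dosage_kind Dosage interpretation; inferred as `posterior_mean` if
#'   any value is non-integer and the argument is missing.
#' @return A `geno_matrix`.
#' @export
read_dosage_csv <- function(path, dosage_kind = NULL) {
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         colClasses = "character")
  markers <- names(raw)[-1]
  meta_rows <- match(c("chrom", "pos", "ref_alt"), raw[[1]])
  if (any(is.na(meta_rows[1:2]))) {
    stop("dosage CSV must contain 'chrom' and 'pos' metadata rows")
  }
  chrom <- as.character(raw[meta_rows[1], -1])
  pos <- as.numeric(raw[meta_rows[2], -1])
  ref <- alt <- rep(NA_character_, length(markers))
  if (!is.na(meta_rows[3])) {
    ra <- strsplit(as.character(raw[meta_rows[3], -1]), "/", fixed = TRUE)
    ref <- vapply(ra, function(x) if (length(x)) x[1] else NA_character_, "")
    alt <- vapply(ra, function(x) if (length(x) > 1) x[2] else NA_character_, "")
  }
  body <- raw[-stats::na.omit(meta_rows), , drop = FALSE]
  samples <- body[[1]]
  d <- as.matrix(body[, -1, drop = FALSE])
  d[d == ""] <- NA
  storage.mode(d) <- "double"
  rownames(d) <- samples
  colnames(d) <- markers
  if (is.null(dosage_kind)) {
    dosage_kind <- if (any(abs(d - round(d)) > 1e-8, na.rm = TRUE)) {
      "posterior_mean"
    } else "most_probable"
  }
  info <- data.frame(marker = markers, chrom = chrom, pos = pos,
                     ref = ref, alt = alt, stringsAsFactors = FALSE)
  geno_matrix(d, info, dosage_kind = dosage_kind)
}
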