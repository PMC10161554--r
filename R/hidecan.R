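#' Chromosome layout
#'
#' @param chrom Ordered chromosome labels (unique).
#' @param length_bp Chromosome lengths in base pairs (> 0).
#' @return A `chromosome_layout` data frame.
#' @export
chromosome_layout <- function(chrom, length_bp) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) stop("chromosome labels must be unique")
  if (any(length_bp <= 0)) stop("chromosome lengths must be positive")
  structure(data.frame(chrom = chrom, length_bp = as.numeric(length_bp),
                       stringsAsFactors = FALSE),
            class = c("chromosome_layout", "data.frame"))
}

#' Read a chromosome layout from a two-column text file
#' @param path Whitespace- or comma-delimited file: chromosome, length (bp).
#' @return A `chromosome_layout`.
#' @export
read_chromosome_layout <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           col.names = c("chrom", "length_bp"),
                           colClasses = c("character", "numeric"))
  chromosome_layout(tab$chrom, tab$length_bp)
}

#' Assemble the tidy HIDECAN layer table
#'
#' Builds the layered table behind a HIDECAN plot: high-scoring GWAS markers
#' (score strictly above `marker_min_score`; markers present in several
#' result sets are deduplicated keeping the best score), significant DE
#' genes (adjusted p strictly below `de_alpha` and absolute log2 fold change
#' at least `min_abs_log2fc`; positioned at their interval midpoint), and
#' candidate genes taken verbatim.
#'
#' @param gwas A `gwas_result` or list of them (may be `NULL`).
#' @param de DE result data frame with `gene_id`, `chromosome`, `start`,
#'   `end`, `log2_fold_change`, `adjusted_p` (may be `NULL`).
#' @param candidates Data frame with `gene`, `chromosome`, `position` and
#'   optionally `source` (may be `NULL`).
#' @param layout A [chromosome_layout()].
#' @param marker_min_score GWAS score threshold (strict).
#' @param de_alpha Adjusted-p threshold (strict).
#' @param min_abs_log2fc Minimum absolute log2 fold change.
#' @return A `hidecan_data` data frame with columns `chromosome`,
#'   `position`, `layer` (`marker`/`de_gene`/`candidate`), `label`, `value`,
#'   `source_id`, sorted by (chromosome, position).
#' @export
build_hidecan_data <- function(gwas = NULL, de = NULL, candidates = NULL,
                               layout, marker_min_score = 4,
                               de_alpha = 0.05, min_abs_log2fc = 0) {
  rows <- list()
  if (!is.null(gwas)) {
    if (inherits(gwas, "gwas_result")) gwas <- list(gwas)
    tabs <- lapply(gwas, function(r) {
      cbind(r$scores[, c("marker", "chrom", "pos", "score")],
            source_id = paste(r$setting, r$model, sep = "|"))
    })
    all_scores <- do.call(rbind, tabs)
    all_scores <- all_scores[!is.na(all_scores$score), , drop = FALSE]
    if (nrow(all_scores)) {
      best <- all_scores[order(all_scores$marker, -all_scores$score), ]
      best <- best[!duplicated(best$marker), , drop = FALSE]
      best <- best[best$score > marker_min_score, , drop = FALSE]
      if (nrow(best)) {
        rows$marker <- data.frame(
          chromosome = best$chrom, position = best$pos, layer = "marker",
          label = best$marker, value = best$score,
          source_id = best$source_id, stringsAsFactors = FALSE)
      }
    }
  }
  if (!is.null(de) && nrow(de)) {
    keep <- !is.na(de$adjusted_p) & de$adjusted_p < de_alpha &
      abs(de$log2_fold_change) >= min_abs_log2fc
    dk <- de[keep, , drop = FALSE]
    if (nrow(dk)) {
      rows$de_gene <- data.frame(
        chromosome = as.character(dk$chromosome),
        position = (dk$start + dk$end) / 2, layer = "de_gene",
        label = dk$gene_id, value = dk$log2_fold_change,
        source_id = "de", stringsAsFactors = FALSE)
    }
  }
  if (!is.null(candidates) && nrow(candidates)) {
    rows$candidate <- data.frame(
      chromosome = as.character(candidates$chromosome),
      position = candidates$position, layer = "candidate",
      label = candidates$gene, value = NA_real_,
      source_id = candidates$source %||% "literature",
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(chromosome = character(0), position = numeric(0),
               layer = character(0), label = character(0),
               value = numeric(0), source_id = character(0),
               stringsAsFactors = FALSE)
  }
  bad <- !out$chromosome %in% layout$chrom
  if (any(bad)) {
    stop("chromosome label(s) absent from layout: ",
         paste(unique(out$chromosome[bad]), collapse = ", "),
         " (rows ", paste(utils::head(which(bad), 10), collapse = ", "), ")")
  }
  out <- out[order(out$chromosome, out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hidecan_data", "data.frame")
  out
}

#' Render a HIDECAN plot
#'
#' One horizontal track per chromosome with genomic position on the x axis
#' scaled to the true chromosome length; the marker, DE-gene and candidate
#' layers are stacked within each track with distinct shapes and colours.
#' The tidy layer table is always written as a CSV sidecar next to the
#' image, which makes reruns byte-comparable.
#'
#' @param data A `hidecan_data` table.
#' @param layout A [chromosome_layout()].
#' @param file Output image path (`.svg` or `.png`).
#' @param split Optional chromosome label: chromosomes up to and including
#'   it go to a first panel file, the rest to a second (suffix `_2`).
#' @param width,height Device size in inches.
#' @return Invisibly, a list with `image` (paths) and `csv` (sidecar path).
#' @export
plot_hidecan <- function(data, layout, file, split = NULL, width = 9,
                         height = 7) {
  if (nrow(layout) == 0) stop("layout has zero chromosomes; nothing to render")
  csv_path <- paste0(sub("\\.(svg|png)$", "", file), "_data.csv")
  utils::write.csv(as.data.frame(data), csv_path, row.names = FALSE)

  render_one <- function(dat, lay, path) {
    lay$chrom <- factor(lay$chrom, levels = lay$chrom)
    dat$chromosome <- factor(dat$chromosome, levels = levels(lay$chrom))
    dat$layer <- factor(dat$layer,
                        levels = c("marker", "de_gene", "candidate"))
    p <- ggplot2::ggplot() +
      ggplot2::geom_segment(
        data = lay,
        ggplot2::aes(x = 0, xend = .data$length_bp / 1e6, y = 0, yend = 0),
        linewidth = 2, colour = "grey85") +
      ggplot2::geom_point(
        data = dat,
        ggplot2::aes(x = .data$position / 1e6,
                     y = as.integer(.data$layer),
                     colour = .data$layer, shape = .data$layer),
        size = 2) +
      ggplot2::facet_grid(rows = ggplot2::vars(.data$chromosome),
                          switch = "y") +
      ggplot2::scale_colour_manual(
        values = c(marker = "#D55E00", de_gene = "#0072B2",
                   candidate = "#009E73"), drop = FALSE) +
      ggplot2::scale_shape_manual(
        values = c(marker = 17, de_gene = 16, candidate = 15),
        drop = FALSE) +
      ggplot2::scale_y_continuous(limits = c(-0.5, 3.5), breaks = NULL) +
      ggplot2::labs(x = "Position (Mb)", y = NULL, colour = "Layer",
                    shape = "Layer") +
      ggplot2::theme_minimal() +
      ggplot2::theme(strip.text.y.left = ggplot2::element_text(angle = 0),
                     panel.grid.minor = ggplot2::element_blank())
    ext <- tolower(sub(".*\\.", "", path))
    if (ext == "svg") {
      grDevices::svg(path, width = width, height = height)
    } else {
      grDevices::png(path, width = width * 100, height = height * 100,
                     res = 100)
    }
    print(p)
    grDevices::dev.off()
    path
  }

  images <- if (is.null(split)) {
    render_one(data, layout, file)
  } else {
    cut_idx <- match(as.character(split), layout$chrom)
    if (is.na(cut_idx)) stop("split chromosome not in layout")
    first <- layout$chrom[seq_len(cut_idx)]
    lay1 <- layout[layout$chrom %in% first, , drop = FALSE]
    lay2 <- layout[!layout$chrom %in% first, , drop = FALSE]
    f2 <- sub("(\\.[a-zA-Z]+)$", "_2\\1", file)
    c(render_one(data[data$chromosome %in% first, , drop = FALSE],
                 lay1, file),
      if (nrow(lay2)) render_one(
        data[!data$chromosome %in% first, , drop = FALSE], lay2, f2))
  }
  invisible(list(image = images, csv = csv_path))
}

#' Colocalization windows between high-scoring markers and DE genes
#'
#' Chains markers and DE genes on the same chromosome whose pairwise
#' distance is within `window_bp` (single linkage) and reports the maximal
#' regions containing at least one marker and one DE gene. Region bounds are
#' the member positions rounded outward to 0.1 Mb. The windowing rule is a
#' formalisation of a narrative colocalization notion, and outputs are
#' labelled as window-based regions.
#'
#' @param data A `hidecan_data` table with marker and de_gene layers.
#' @param window_bp Maximum marker-gene distance within a region.
#' @return Data frame with `chromosome`, `start`, `end`, `markers`, `genes`
#'   (comma-separated labels).
#' @export
colocalization_windows <- function(data, window_bp = 1e6) {
  out <- list()
  for (ch in unique(data$chromosome)) {
    dd <- data[data$chromosome == ch, , drop = FALSE]
    mk <- dd[dd$layer == "marker", , drop = FALSE]
    gn <- dd[dd$layer == "de_gene", , drop = FALSE]
    if (!nrow(mk) || !nrow(gn)) next
    nodes <- rbind(
      data.frame(pos = mk$position, label = mk$label, kind = "marker",
                 stringsAsFactors = FALSE),
      data.frame(pos = gn$position, label = gn$label, kind = "gene",
                 stringsAsFactors = FALSE))
    n <- nrow(nodes)
    comp <- seq_len(n)                      # union-find over nodes
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    for (i in which(nodes$kind == "marker")) {
      for (j in which(nodes$kind == "gene")) {
        if (abs(nodes$pos[i] - nodes$pos[j]) <= window_bp) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) comp[ri] <- rj
        }
      }
    }
    roots <- vapply(seq_len(n), find, 0L)
    for (r in unique(roots)) {
      members <- nodes[roots == r, , drop = FALSE]
      if (!any(members$kind == "marker") || !any(members$kind == "gene")) {
        next
      }
      out[[length(out) + 1]] <- data.frame(
        chromosome = ch,
        start = floor(min(members$pos) / 1e5) * 1e5,
        end = ceiling(max(members$pos) / 1e5) * 1e5,
        markers = paste(members$label[members$kind == "marker"],
                        collapse = ","),
        genes = paste(members$label[members$kind == "gene"], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chromosome = character(0), start = numeric(0),
                      end = numeric(0), markers = character(0),
                      genes = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$chromosome, res$start), , drop = FALSE]
}
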