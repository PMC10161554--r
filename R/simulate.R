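#' Default multi-cross half-sib design
#'
#' A 22-cross design with two shared first parents and 158 progeny in total,
#' mirroring the scale and half-sib structure of a potato breeding panel in
#' which many second parents are each crossed to one of two related common
#' parents.
#'
#' @return Data frame with columns `parent1`, `parent2`, `n_progeny`.
#' @export
default_cross_design <- function() {
  data.frame(
    parent1 = c(rep("P1", 7), rep("P2", 16)),
    parent2 = c(paste0("Q", 1:7), paste0("R", 1:16)),
    n_progeny = c(7, 5, 9, 3, 5, 5, 6,
                  11, 10, 13, 16, 4, 10, 3, 2, 7, 5, 8, 7, 2, 8, 6, 6),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic half-sib panel: genome shape, founder
#' allele frequencies (optionally split into two diverged pools to plant
#' population structure), planted QTLs, phenotype heritability and replicate
#' structure, missingness, and the negative-binomial expression block.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param markers_per_chromosome Markers simulated per chromosome.
#' @param chromosome_length_bp Chromosome length in base pairs.
#' @param freq_range Range the founder alternate-allele frequencies are
#'   drawn from.
#' @param pool_shift Allele-frequency divergence between the two founder
#'   pools (0 disables planted structure).
#' @param qtl Data frame with `chrom_index`, `marker_index`, `model`,
#'   `effect` describing planted QTLs (may be empty).
#' @param h2 Narrow-sense heritability of the latent genetic value.
#' @param n_replicates,n_tubers Replicate structure of the phenotype.
#' @param replicate_sd,tuber_sd Replicate- and tuber-level noise SDs on the
#'   latent scale.
#' @param score_probs Population quantile bin widths used to discretise the
#'   latent phenotype to the 0--5 bruising scale (sums to 1).
#' @param missing_rate Genotype missingness rate.
#' @param ld_block_size Consecutive markers per planted LD block (1 = no
#'   planted LD); within a block, dosage columns are copies of the block
#'   head with entries independently resampled at `ld_flip_rate`.
#' @param ld_flip_rate Per-entry resampling rate inside an LD block.
#' @param n_genes,n_de,de_log2fc,nb_dispersion,libsize_range Expression
#'   block: gene count, planted DE genes, their absolute log2 fold change,
#'   NB dispersion (0 = Poisson) and library-size factor range.
#' @param seed Mandatory integer seed.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_chromosomes = 5,
                              markers_per_chromosome = 60,
                              chromosome_length_bp = 6e7,
                              freq_range = c(0.1, 0.9),
                              pool_shift = 0,
                              qtl = NULL,
                              h2 = 0.5,
                              n_replicates = 2,
                              n_tubers = 3,
                              replicate_sd = 0.3,
                              tuber_sd = 0.3,
                              score_probs = c(0.25, 0.25, 0.2, 0.15, 0.1,
                                              0.05),
                              missing_rate = 0,
                              ld_block_size = 1,
                              ld_flip_rate = 0.1,
                              n_genes = 2000,
                              n_de = 50,
                              de_log2fc = 2,
                              nb_dispersion = 0.1,
                              libsize_range = c(0.7, 1.3),
                              seed = 1) {
  stopifnot(h2 >= 0, h2 <= 1, missing_rate >= 0, missing_rate <= 1,
            abs(sum(score_probs) - 1) < 1e-8, is.numeric(seed))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an autotetraploid cross
#'
#' Each parent transmits a two-allele gamete whose alternate dosage follows
#' Hypergeometric(4, parent dosage, 2) — random bivalent pairing without
#' double reduction. Progeny dosage is the sum of the two gametes; markers
#' are independent (no recombination map).
#'
#' @param parent1_dosages,parent2_dosages Integer dosage vectors (0--4).
#' @param n_progeny Number of offspring.
#' @param seed Integer seed.
#' @return Integer matrix, progeny x markers.
#' @export
simulate_cross <- function(parent1_dosages, parent2_dosages, n_progeny,
                           seed = 1) {
  if (any(parent1_dosages < 0 | parent1_dosages > 4 |
          parent2_dosages < 0 | parent2_dosages > 4, na.rm = TRUE) ||
      any(parent1_dosages != round(parent1_dosages), na.rm = TRUE)) {
    stop("parental dosages must be integers in 0..4")
  }
  m <- length(parent1_dosages)
  stopifnot(length(parent2_dosages) == m)
  with_seed(seed, {
    g1 <- vapply(seq_len(m), function(j) {
      stats::rhyper(n_progeny, parent1_dosages[j], 4 - parent1_dosages[j], 2)
    }, numeric(n_progeny))
    g2 <- vapply(seq_len(m), function(j) {
      stats::rhyper(n_progeny, parent2_dosages[j], 4 - parent2_dosages[j], 2)
    }, numeric(n_progeny))
    out <- g1 + g2
    if (n_progeny == 1) out <- matrix(out, nrow = 1)
    out
  })
}

#' Simulate a half-sib genotype panel
#'
#' Founder genotypes are binomial dosages drawn from per-marker allele
#' frequencies; with `pool_shift > 0` the founders are split into two
#' diverged pools (first parents in pool 1 and 2 respectively, second
#' parents alternating), planting detectable population structure. Crosses
#' follow the design via [simulate_cross()]; optional LD blocks and
#' missingness are applied afterwards.
#'
#' @param design Cross design data frame (see [default_cross_design()]).
#' @param config A [simulation_config()].
#' @return List with `geno` (a [geno_matrix()] of progeny plus parents),
#'   `truth` (QTL table, subpopulation labels, parent dosages, LD blocks).
#' @export
simulate_panel <- function(design, config) {
  if (sum(design$n_progeny) == 0) stop("design has zero total progeny")
  cfg <- config
  n_chr <- cfg$n_chromosomes
  mpc <- cfg$markers_per_chromosome
  m <- n_chr * mpc
  with_seed(cfg$seed, {
    chrom <- rep(paste0("chr", seq_len(n_chr)), each = mpc)
    pos <- as.vector(vapply(seq_len(n_chr), function(i) {
      sort(sample.int(cfg$chromosome_length_bp, mpc))
    }, numeric(mpc)))
    marker <- paste0(chrom, "_", pos)

    parents <- unique(c(design$parent1, design$parent2))
    first_parents <- unique(design$parent1)
    pool <- stats::setNames(rep(1L, length(parents)), parents)
    if (cfg$pool_shift > 0) {
      second <- setdiff(parents, first_parents)
      pool[first_parents] <- seq_along(first_parents) %% 2L + 1L
      pool[second] <- seq_along(second) %% 2L + 1L
    }
    f <- stats::runif(m, cfg$freq_range[1], cfg$freq_range[2])
    f1 <- pmin(pmax(f - cfg$pool_shift / 2, 0.02), 0.98)
    f2 <- pmin(pmax(f + cfg$pool_shift / 2, 0.02), 0.98)
    parent_dosage <- t(vapply(parents, function(p) {
      pf <- if (pool[p] == 1L) f1 else f2
      stats::rbinom(m, 4, pf)
    }, numeric(m)))
    rownames(parent_dosage) <- parents
    colnames(parent_dosage) <- marker

    prog_rows <- list()
    prog_ids <- character(0)
    subpop <- character(0)
    for (i in seq_len(nrow(design))) {
      p1 <- design$parent1[i]; p2 <- design$parent2[i]
      np <- design$n_progeny[i]
      if (np == 0) next
      off <- simulate_cross(parent_dosage[p1, ], parent_dosage[p2, ], np,
                            seed = sample.int(2^30, 1))
      ids <- paste0(p1, "x", p2, "_", seq_len(np))
      prog_rows[[length(prog_rows) + 1]] <- off
      prog_ids <- c(prog_ids, ids)
      subpop <- c(subpop, rep(paste0("pool", pool[p1], pool[p2]), np))
    }
    dosage <- do.call(rbind, prog_rows)
    rownames(dosage) <- prog_ids

    ld_blocks <- NULL
    if (cfg$ld_block_size > 1) {
      block <- (seq_len(m) - 1) %/% cfg$ld_block_size
      for (b in unique(block)) {
        idx <- which(block == b)
        head_col <- dosage[, idx[1]]
        for (j in idx[-1]) {
          flip <- stats::runif(nrow(dosage)) < cfg$ld_flip_rate
          col <- head_col
          col[flip] <- stats::rbinom(sum(flip), 4, f[j])
          dosage[, j] <- col
        }
      }
      ld_blocks <- block
    }

    qtl_truth <- NULL
    if (!is.null(cfg$qtl) && nrow(cfg$qtl)) {
      gi <- (cfg$qtl$chrom_index - 1) * mpc + cfg$qtl$marker_index
      qtl_truth <- data.frame(marker = marker[gi],
                              model = cfg$qtl$model,
                              effect = cfg$qtl$effect,
                              stringsAsFactors = FALSE)
    }

    full <- rbind(dosage, parent_dosage)
    subpop_all <- c(subpop,
                    paste0("pool", pool[parents], pool[parents]))
    names(subpop_all) <- c(prog_ids, parents)
    if (cfg$missing_rate > 0) {
      drop <- stats::runif(length(full)) < cfg$missing_rate
      full[drop] <- NA
    }
    info <- data.frame(marker = marker, chrom = chrom, pos = pos,
                       ref = "A", alt = "T", qual = NA_real_,
                       stringsAsFactors = FALSE)
    g <- geno_matrix(full, info, dosage_kind = "most_probable")
    list(geno = g,
         truth = list(qtl = qtl_truth,
                      subpop = subpop_all,
                      progeny = prog_ids,
                      parents = parents,
                      parent_dosage = parent_dosage,
                      allele_freq = f,
                      pool = pool,
                      ld_blocks = ld_blocks))
  })
}

#' Truth-based soft membership matrix for a simulated panel
#'
#' The membership an ideal admixture analysis would recover: founders are
#' assigned one-hot to their pool, progeny get the average of their two
#' parents' memberships. Useful as the Q matrix of the `Q_struct` settings
#' when no external admixture run is available.
#'
#' @param panel Output of [simulate_panel()].
#' @return Membership matrix (samples x pools, rows sum to 1).
#' @export
truth_membership <- function(panel) {
  pool <- panel$truth$pool
  pools <- sort(unique(pool))
  samples <- rownames(panel$geno$dosage)
  mem <- matrix(0, nrow = length(samples), ncol = length(pools),
                dimnames = list(samples, paste0("pool", pools)))
  for (s in samples) {
    if (s %in% names(pool)) {
      mem[s, match(pool[s], pools)] <- 1
    } else {
      ps <- strsplit(sub("_\\d+$", "", s), "x")[[1]]
      mem[s, match(pool[ps[1]], pools)] <-
        mem[s, match(pool[ps[1]], pools)] + 0.5
      mem[s, match(pool[ps[2]], pools)] <-
        mem[s, match(pool[ps[2]], pools)] + 0.5
    }
  }
  mem
}

#' Simulate a replicate-structured bruising phenotype
#'
#' The latent genotype value is the sum of planted QTL effects (each on its
#' genetic-model encoding), a polygenic term drawn from the panel kinship,
#' and residual noise scaled so the genetic fraction of the latent variance
#' equals `h2`. Latent tuber values add replicate and tuber noise and are
#' discretised to the 0--5 scale at fixed population quantiles, so the group
#' sizes of the bruising scale are controllable.
#'
#' @param g A [geno_matrix()] of the phenotyped samples.
#' @param qtl QTL truth table (`marker`, `model`, `effect`) or `NULL`.
#' @param h2 Fraction of the latent genotype-level variance explained by the
#'   planted QTLs (0 gives a pure-noise phenotype).
#' @param config A [simulation_config()] (replicate structure, bin widths).
#' @param seed Integer seed.
#' @param polygenic_h2 Fraction of the latent variance carried by the
#'   kinship-distributed polygenic term; `h2 + polygenic_h2` must be <= 1.
#' @return List with `scores` (data frame `genotype`, `replicate`, `tuber`,
#'   `score`) and `latent` (named genotype-level latent values).
#' @export
simulate_phenotype <- function(g, qtl, h2, config, seed = 1,
                               polygenic_h2 = 0) {
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  if (polygenic_h2 < 0 || h2 + polygenic_h2 > 1) {
    stop("h2 + polygenic_h2 must lie in [0, 1]")
  }
  cfg <- config
  n <- nrow(g$dosage)
  samples <- rownames(g$dosage)
  with_seed(seed, {
    gv <- numeric(n)
    if (!is.null(qtl) && nrow(qtl) && h2 > 0) {
      for (i in seq_len(nrow(qtl))) {
        x <- g$dosage[, match(qtl$marker[i], g$info$marker)]
        x[is.na(x)] <- mean(x, na.rm = TRUE)
        enc <- encode_dosage(qtl$model[i], x)
        gv <- gv + qtl$effect[i] * enc[, 1]
      }
    }
    vq <- stats::var(gv)
    # latent variance budget: QTLs take h2, polygenic polygenic_h2, noise the
    # rest; scaled empirically so realised shares match the request
    total <- if (vq > 0 && h2 > 0) vq / h2 else 1
    u <- numeric(n)
    if (polygenic_h2 > 0) {
      Kk <- compute_kinship(g, loco = FALSE)$global
      ev <- eigen(Kk, symmetric = TRUE)
      L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
      u <- drop(L %*% stats::rnorm(n))
      u <- u / stats::sd(u) * sqrt(polygenic_h2 * total)
    }
    if (vq == 0 || h2 == 0) gv <- numeric(n)
    ve <- max(total * (1 - h2 - polygenic_h2), 1e-12)
    latent <- gv + u + stats::rnorm(n, sd = sqrt(ve))
    names(latent) <- samples

    recs <- expand.grid(tuber = seq_len(cfg$n_tubers),
                        replicate = seq_len(cfg$n_replicates),
                        genotype = samples, stringsAsFactors = FALSE)
    rep_eff <- stats::rnorm(n * cfg$n_replicates, sd = cfg$replicate_sd)
    names(rep_eff) <- paste(rep(samples, each = cfg$n_replicates),
                            seq_len(cfg$n_replicates), sep = ".")
    lat_tuber <- latent[recs$genotype] +
      rep_eff[paste(recs$genotype, recs$replicate, sep = ".")] +
      stats::rnorm(nrow(recs), sd = cfg$tuber_sd)
    cuts <- stats::quantile(lat_tuber, probs = cumsum(cfg$score_probs))
    score <- findInterval(lat_tuber, cuts[-length(cuts)], left.open = TRUE)
    scores <- data.frame(genotype = recs$genotype,
                         replicate = recs$replicate,
                         tuber = recs$tuber,
                         score = score, stringsAsFactors = FALSE)
    list(scores = scores, latent = latent)
  })
}

#' Simulate negative-binomial expression counts with planted DE genes
#'
#' Gene baselines are log-normal; counts are negative binomial with the
#' configured dispersion (Poisson when 0) scaled by per-sample library-size
#' factors. The first `n_de` genes are differentially expressed between the
#' groups with alternating direction and group mean ratio
#' `2^de_log2fc`.
#'
#' @param groups Named character vector mapping sample id to `"low"` or
#'   `"high"` (>= 2 samples per group).
#' @param config A [simulation_config()] (expression block).
#' @param seed Integer seed.
#' @return List with `counts` (genes x samples), `truth` (DE gene ids and
#'   directions) and `size_factors`.
#' @export
simulate_expression <- function(groups, config, seed = 1) {
  cfg <- config
  if (cfg$n_de > cfg$n_genes) stop("n_de cannot exceed n_genes")
  samples <- names(groups)
  if (sum(groups == "low") < 2 || sum(groups == "high") < 2) {
    stop("need at least 2 samples per group")
  }
  with_seed(seed, {
    ng <- cfg$n_genes
    base <- stats::rlnorm(ng, meanlog = log(100), sdlog = 1)
    sf <- stats::runif(length(samples), cfg$libsize_range[1],
                       cfg$libsize_range[2])
    names(sf) <- samples
    direction <- integer(ng)
    if (cfg$n_de > 0) {
      direction[seq_len(cfg$n_de)] <- rep(c(1L, -1L),
                                          length.out = cfg$n_de)
    }
    counts <- matrix(0L, nrow = ng, ncol = length(samples),
                     dimnames = list(paste0("gene_", seq_len(ng)), samples))
    hi <- groups[samples] == "high"
    for (jj in seq_along(samples)) {
      mu <- base * sf[jj]
      if (hi[jj]) mu <- mu * 2^(direction * cfg$de_log2fc)
      counts[, jj] <- if (cfg$nb_dispersion > 0) {
        stats::rnbinom(ng, mu = mu, size = 1 / cfg$nb_dispersion)
      } else {
        stats::rpois(ng, lambda = mu)
      }
    }
    truth <- data.frame(gene_id = rownames(counts)[direction != 0],
                        direction = direction[direction != 0],
                        stringsAsFactors = FALSE)
    list(counts = counts, truth = truth, size_factors = sf)
  })
}
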