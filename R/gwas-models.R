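#' The eight tetraploid genetic models
#'
#' @return Character vector of model names.
#' @export
genetic_models <- function() {
  c("general", "additive", "1-dom-ref", "1-dom-alt",
    "2-dom-ref", "2-dom-alt", "diplo-general", "diplo-additive")
}

#' Encode tetraploid dosages under a genetic model
#'
#' Maps alternate-allele dosages (0--4) to the marker design column(s) of a
#' genetic model. Dosage here counts alternate alleles, so the reference
#' dosage is `4 - d`:
#' * `additive`: the dosage itself (raw real values allowed);
#' * `1-dom-ref`: 1 if at least one reference copy (d <= 3);
#' * `1-dom-alt`: 1 if at least one alternate copy (d >= 1);
#' * `2-dom-ref`: 1 if at least two reference copies (d <= 2);
#' * `2-dom-alt`: 1 if at least two alternate copies (d >= 2);
#' * `diplo-additive`: heterozygotes share one effect halfway between the
#'   homozygotes (0 -> 0, 1..3 -> 1, 4 -> 2; real dosages interpolated
#'   piecewise-linearly);
#' * `diplo-general`: indicator columns for heterozygote (1--3) and
#'   alternate homozygote (4);
#' * `general`: indicator columns for each observed dosage level against the
#'   lowest observed level.
#'
#' Threshold-type models round real-valued (posterior-mean) dosages to the
#' nearest integer first; `additive` and `diplo-additive` use them raw.
#'
#' @param model One of [genetic_models()].
#' @param d Numeric dosage vector in `[0, 4]` (`NA` allowed).
#' @return Numeric matrix with one column per model degree of freedom.
#' @export
encode_dosage <- function(model, d) {
  model <- match.arg(model, genetic_models())
  if (any(d < 0 | d > 4, na.rm = TRUE)) stop("dosages must lie in [0, 4]")
  di <- round(d)  # threshold models act on integer dosage classes
  out <- switch(
    model,
    "additive" = matrix(d, dimnames = list(NULL, "additive")),
    "1-dom-ref" = matrix(as.numeric(di <= 3),
                         dimnames = list(NULL, "dom_ref_1")),
    "1-dom-alt" = matrix(as.numeric(di >= 1),
                         dimnames = list(NULL, "dom_alt_1")),
    "2-dom-ref" = matrix(as.numeric(di <= 2),
                         dimnames = list(NULL, "dom_ref_2")),
    "2-dom-alt" = matrix(as.numeric(di >= 2),
                         dimnames = list(NULL, "dom_alt_2")),
    "diplo-additive" = {
      e <- ifelse(d <= 1, d, ifelse(d <= 3, 1, d - 2))
      matrix(e, dimnames = list(NULL, "diplo_additive"))
    },
    "diplo-general" = cbind(het = as.numeric(di >= 1 & di <= 3),
                            hom_alt = as.numeric(di == 4)),
    "general" = {
      lev <- sort(unique(di[!is.na(di)]))
      if (length(lev) <= 1) {
        matrix(numeric(length(d)), ncol = 1,
               dimnames = list(NULL, "general_0"))
      } else {
        cols <- lev[-1]
        mat <- vapply(cols, function(l) as.numeric(di == l),
                      numeric(length(d)))
        if (length(d) == 1) mat <- matrix(mat, nrow = 1)
        colnames(mat) <- paste0("general_", cols)
        mat
      }
    }
  )
  out[is.na(d), ] <- NA_real_
  out
}

#' Define a population setting for the GWAS mixed model
#'
#' A population setting pairs a kinship choice with optional subpopulation
#' membership covariates:
#' * `naive`: identity kinship, no covariates;
#' * `K`: realised-relationship kinship only;
#' * `Q`: identity kinship plus membership covariates;
#' * `K+Q`: both.
#'
#' The last membership column is dropped when building covariates (rows sum
#' to one, so it is collinear with the intercept).
#'
#' @param name Setting label (e.g. `"naive"`, `"K"`, `"Q_struct"`,
#'   `"K+Q_dapc"`).
#' @param uses_kinship Does the setting use the realised-relationship
#'   kinship (otherwise identity)?
#' @param membership Optional membership matrix (samples x groups, rows sum
#'   to 1).
#' @return A `population_setting` object.
#' @export
population_setting <- function(name, uses_kinship = FALSE,
                               membership = NULL) {
  if (!is.null(membership)) {
    membership <- as.matrix(membership)
    if (max(abs(rowSums(membership) - 1)) > 1e-6) {
      stop("membership rows must sum to 1")
    }
  }
  structure(list(name = name, uses_kinship = uses_kinship,
                 membership = membership),
            class = "population_setting")
}

#' Build the six standard population settings
#'
#' @param q_struct Membership matrix from an admixture analysis (e.g.
#'   imported STRUCTURE output).
#' @param q_dapc Membership matrix from a DAPC fit.
#' @return Named list of six `population_setting` objects: naive, K,
#'   Q_struct, Q_dapc, K+Q_struct, K+Q_dapc.
#' @export
standard_settings <- function(q_struct, q_dapc) {
  list(
    "naive" = population_setting("naive", FALSE, NULL),
    "K" = population_setting("K", TRUE, NULL),
    "Q_struct" = population_setting("Q_struct", FALSE, q_struct),
    "Q_dapc" = population_setting("Q_dapc", FALSE, q_dapc),
    "K+Q_struct" = population_setting("K+Q_struct", TRUE, q_struct),
    "K+Q_dapc" = population_setting("K+Q_dapc", TRUE, q_dapc)
  )
}

# covariate matrix for a setting: intercept + membership minus last column
setting_covariates <- function(setting, samples) {
  X <- matrix(1, nrow = length(samples), ncol = 1,
              dimnames = list(samples, "(Intercept)"))
  q <- setting$membership
  if (!is.null(q)) {
    if (!is.null(rownames(q))) {
      missing <- setdiff(samples, rownames(q))
      if (length(missing)) {
        stop("membership matrix lacks sample(s): ",
             paste(utils::head(missing, 5), collapse = ", "))
      }
      q <- q[samples, , drop = FALSE]
    }
    if (ncol(q) > 1) {
      X <- cbind(X, q[, -ncol(q), drop = FALSE])
    }
  }
  X
}
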