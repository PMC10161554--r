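---
title: "Models and methods behind tetragwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tetragwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetragwas)
```

`tetragwas` analyses quantitative traits in autotetraploid panels where
every individual carries 0–4 copies of the alternate allele at each
marker. This vignette is the package's own account of the models it
implements, the numerical choices it makes, and what its synthetic test
bed does and does not emulate. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## Genotype filtering

Dosage is always the alternate-allele count, so the reference dosage is
`4 - d`. Three variant-level rules are applied in a fixed order
(missingness, then QD, then MAF), each marker counted against the first
rule it fails so the filter report is conserved:

* **Missingness.** A variant passes while its missing fraction is at most
  10%. The boundary is deliberately asymmetric with the sample filter: a
  *sample* missing strictly more than 10% of markers is removed, while a
  *variant* with exactly 10% missing samples is kept. Both conventions are
  documented on the functions and the variant side can be flipped with
  `strict_missing = TRUE`.
* **QD.** QualByDepth is the variant quality divided by the summed read
  depth over non-homozygous samples (dosage 1–3). When no heterozygous
  sample exists or total depth is zero the score is undefined and the
  variant fails, with the reason recorded. Depths are used exactly as read
  from the VCF — no recalibration is attempted.
* **MAF.** With `f` the mean dosage divided by 4 over non-missing samples,
  `MAF = min(f, 1 - f)` must be *strictly* greater than 0.01.

Multi-allelic and indel records are dropped whole, never decomposed:
decomposition would require re-phasing tetraploid calls, which the
upstream callers this package consumes do not provide reliably.

## LD pruning

For each chromosome, markers are sorted by position and a start variant
is drawn uniformly using the supplied seed (recorded in the output; each
chromosome derives its own seed from the global one so chromosomes stay
independent). The retained set `S` starts at the start variant. Candidates
are scanned rightwards to the chromosome end and then leftwards from the
variant preceding the start, against the same growing set `S`. A candidate
is dropped when *any* retained variant within the window (inclusive,
`|Δpos| ≤ 100` kb by default) has `r² > 0.5` with it — the whole windowed
retained set is tested, not only the physically nearest member, because a
candidate can be in strong LD with a retained variant that is not its
neighbour in `S`.

`r²` is the squared Pearson correlation over complete pairs. With fewer
than two complete pairs, or a monomorphic column among the complete pairs,
`r²` is undefined and treated as "no linkage" so the candidate is kept;
the alternative (dropping on undefined `r²`) is exposed as
`drop_undefined = TRUE`. Treating undefined as zero is the conservative
choice for downstream association testing: it never discards a marker on
evidence that does not exist.

## Population structure

**PCA** operates on per-marker mean-imputed, column-centred dosages.
Mean imputation shrinks missing calls towards the allele-frequency
expectation and is the same convention used for kinship and for marker
tests, so all three see an identical design matrix.

**Cluster count.** k-means is run for each candidate count and scored
with `BIC(k) = n log(WSS/n) + k log(n)`; the smallest count attaining the
minimum is returned. This criterion behaves well when within-cluster
variation is spread over many retained components (the situation for
genotype PCA scores, where most retained PCs carry family-level noise a
further split cannot absorb); on low-dimensional, strongly Gaussian scores
it will over-split, which is why the package keeps the full BIC curve in
the output rather than only the argmin.

**Discriminant analysis.** A linear discriminant analysis with equal
priors on the retained PCs; memberships are the Gaussian posteriors under
the pooled within-cluster covariance. The number of PCs is chosen by
stratified 90/10 cross-validation repeated `n_reps` times, scoring
held-out assignment accuracy and the RMSE between posterior membership
and 0/1 truth. The published selection rule for the PC count ("highest
value with high accuracy and low RMSE") carries no numeric criterion, so
the package returns both curves and selects the accuracy argmax with ties
to fewer PCs; users wanting the more permissive rule can apply it to the
emitted curve.

**Admixture post-processing.** The Evanno statistic
`Δ(k) = |mean L(k+1) - 2 mean L(k) + mean L(k-1)| / sd(L(k))` is computed
from replicate log-likelihoods; endpoints carry no value and a zero
replicate standard deviation yields `NA` rather than an error, because a
degenerate replicate set is a property of the runs, not a usage mistake.
Label switching across replicate runs is resolved by maximising total
column-wise correlation against the first run — exhaustively for up to 8
groups (8! assignments is cheap and exact), by Hungarian assignment
beyond. Aligned runs are averaged and rows renormalised.

**Kinship.** `K = MMᵀ` from the column-centred dosage matrix, scaled so
the mean diagonal is 1. Columns are centred but not variance-scaled: the
source model specifies only `MMᵀ`, and variance scaling would up-weight
rare markers in a panel whose allele frequencies are already constrained
by the cross design. The leave-one-chromosome-out matrices exclude the
focal chromosome so a tested marker never contributes to its own
covariance correction; LOCO requires at least two chromosomes and says so.

## The GWAS mixed model

For phenotype vector `y` (normalised BLUEs), covariates `X` (intercept
plus membership columns with the last dropped — memberships are
row-stochastic and otherwise collinear with the intercept), marker design
`S`, and polygenic effects `u` with `Var(u) = σ²g K`,
`Var(ε) = σ²e I`:

* The null model (no marker) is fitted by REML, profiling the single
  ratio `λ = σ²g/σ²e` on the spectral decomposition of `K`. The
  optimiser is Brent's method on `log λ ∈ [-12, 12]`; an optimum at the
  lower boundary collapses to `λ = 0` (pure OLS). For settings without
  kinship, `K` is the identity and no optimisation is needed.
* Variance components are estimated once per (setting, chromosome) and
  reused for every marker on that chromosome — the P3D approximation.
  Exact per-marker REML would multiply run time by the marker count for
  a second-order correction that matters only when a marker explains a
  large variance share, which the F-test then detects anyway.
* Each marker's encoded column(s) are added to the fixed effects and
  tested with a generalised-least-squares F-test in the rotated
  (whitened) coordinates; the numerator degrees of freedom are the rank
  increase, so collinear encodings are handled and fully constant ones are
  skipped with reason `constant_encoding`. p-values are floored at 1e-300
  to keep scores finite.
* Missing dosages are mean-imputed per marker before encoding. This keeps
  the whole-sample rotation valid; the alternative (dropping samples per
  marker) would require a fresh eigendecomposition per missing pattern.
  Threshold-model encodings round real dosages to the nearest integer
  first; additive uses them raw, and the diploidised additive encoding
  interpolates its 0/1/1/1/2 map piecewise-linearly so posterior-mean
  dosages remain usable.

**Inflation.** The inflation factor is the no-intercept regression slope
of sorted observed scores on the expected null order statistics
`-log10(i/(m+1))`, largest on largest. The population setting whose mean
inflation over all genetic models is closest to 1 *from above* is
selected; when every setting is below 1 the closest one is returned with
an explicit flag, since under-correction and over-correction are not
symmetric failures.

**Thresholds.** Benjamini–Hochberg at `α = 0.05` defines the significance
threshold, reported on the score scale as `-log10` of the largest
significant p-value (`Inf` when nothing passes). High-scoring markers are
those with score strictly above 4 (`p < 1e-4`); the strict direction
follows the phrasing that defines the rule via "score above 4".

## Phenotype handling

Bruising scores (0–5 visual scale, tubers within biological replicates
within genotypes) enter the mixed model `score ~ genotype (fixed) +
replicate-in-genotype (random)`; the per-genotype fixed-effect estimates
are the BLUEs. When every genotype–replicate cell holds one observation
the replicate variance is inestimable (confounded with the residual) and
the fit reduces to OLS, which equals the REML limit at zero replicate
variance. BLUEs are then passed through a standardised Yeo–Johnson
transform: the λ maximising the Gaussian profile log-likelihood on
`[-2, 2]` (Brent's method; near-ties resolved to the identity λ = 1),
followed by centring and scaling. Group classification for the expression
contrast uses per-replicate tuber means with inclusive boundaries: ≤ 1 is
low, ≥ 2 is high, between is excluded.

## Expression integration

Genes with five or more samples below 5 reads are removed. The
convenience DE screen (median-of-ratios size factors, Welch t on
`log2(x+1)`, BH adjustment) is plumbing for pipelines without a count
model and is documented as such — it is not a substitute for a negative
binomial DE fit when one is available.

Enrichment uses functional class scoring on gene scores
`-log10(adjusted p)` (floored at 1e-300). The default statistic is the
two-sample Welch t between the set (size `m`) and the background (size
`n_bg`), `t = (mean_set - mean_bg)/sqrt(var_set/m + var_bg/n_bg)`,
one-sided towards enrichment, which is calibrated: random sets drawn from
the background give uniform p-values, as the test suite verifies. The
variant that contrasts the set against a *virtual random set of the same
size* (`var_bg/m` in the denominator) is available as
`virtual_set = TRUE`; it is deliberately conservative — its denominator is
roughly twice the null variance of the numerator, so null rejection rates
fall near 1% at the nominal 5% — and the calibrated default was chosen so
that stated error rates mean what they say.

## HIDECAN and colocalization

The layered table keeps markers whose best score across the supplied
result sets strictly exceeds the threshold (deduplicated by maximum
score), DE genes below the adjusted-p threshold at their interval
midpoint, and candidates verbatim. The plot draws one track per
chromosome, x scaled to true chromosome length, three visually distinct
layers, and always writes the tidy table as a CSV sidecar so reruns are
byte-comparable even though image encoders need not be.

Colocalization is a formalisation of a narrative notion and is labelled
as such: markers and DE genes on a chromosome are chained by single
linkage over marker–gene pairs within 1 Mb, and each connected component
containing both kinds becomes a region, bounds rounded outward to 0.1 Mb.
Gene–gene proximity alone never links a region, since the point of the
report is genomic + transcriptomic co-occurrence.

## The synthetic test bed

The generator's defaults define the study conditions for every test:

* **Cross design.** 23 crosses, two shared first parents, 158 progeny —
  the scale and half-sib structure of a breeding-programme panel.
* **Meiosis.** Each parent transmits a gamete whose alternate dosage is
  Hypergeometric(4, dosage, 2): random bivalent pairing, no double
  reduction. Markers are transmitted independently — there is no
  recombination map, so LD from genetic linkage is *not* emulated; LD for
  pruning tests is planted by copying marker columns with controlled
  per-entry resampling. Consequently, passing tests demonstrate correct
  behaviour of the dosage algebra, the pruning scan and the mixed model,
  not robustness to realistic recombination-driven LD decay.
* **Structure.** Founders split into two pools with allele-frequency
  divergence 0.4 by default, chosen to give PCA-visible but not trivially
  separable structure (a realistic Fst-like shift for related breeding
  pools).
* **Phenotype.** Latent genetic value = planted QTL effects (`h2` of the
  latent variance, empirically scaled) + kinship-distributed polygenic
  term (`polygenic_h2`) + Gaussian noise; replicate and tuber noise (SD
  0.3 each on the latent scale) added, then discretisation to 0–5 at fixed
  population quantiles (default bin mass 25/25/20/15/10/5%, skewed low as
  bruising scores are). Discretisation costs information, which is the
  point: the test bed exercises the pipeline on the scale the phenotype is
  actually recorded on.
* **Expression.** Log-normal baselines, negative-binomial counts
  (dispersion 0.1, Poisson at 0), library-size factors in [0.7, 1.3], 57
  planted DE genes at |log2FC| = 2 with alternating direction, matching
  the study's group sizes of 41 vs 33 in the power checks.

Problem sizes in the test suite (e.g. 100–200 samples, 100–300 markers,
20–100 replicates per property) were chosen as the smallest instances at
which the tested contrasts are statistically stable; the acceptance
script uses the same scales.

## Known limitations

* No recombination map and no double reduction in the simulator.
* Mean imputation everywhere; no genotype-posterior-aware imputation.
* P3D only — no exact per-marker variance-component refit.
* The Bayesian admixture model itself is not run; the package only
  exports its input format, imports its output, and post-processes
  replicate runs.
* Colocalization windows are distance-based; no LD-aware refinement.
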