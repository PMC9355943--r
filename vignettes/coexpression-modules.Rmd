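---
title: "Cell-type co-expression modules and phenotype association: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type co-expression modules and phenotype association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexmod)
```

# Overview

`coexmod` implements a five-stage analysis for linking cell-type-specific
gene programs to histological disease phenotypes: (1) preprocessing of
droplet single-cell counts, (2) robust consensus WGCNA within each cell
type, (3) projection of module activity into a bulk RNA-seq cohort,
(4) covariate-adjusted bootstrap association of activity with ordinal
phenotype grades, and (5) preservation and enrichment testing. This
vignette records the model assumptions, the tunable parameters and their
defaults, the numerical choices, and what the synthetic validation does and
does not demonstrate.

# Preprocessing

Cells are filtered on detected-gene count (default 200–6,000) and
mitochondrial fraction (default ≤ 0.2, genes prefixed `MT-`). These are
droplet-data conventions; the source study design states only post-QC cell
counts, so all three are exposed in `pipeline_config()`.

Single-cell normalization is median-library-size scaling followed by
`log1p`; bulk normalization is the DESeq-style median-of-ratios size factor
(verified against `DESeq2::estimateSizeFactorsForMatrix` in the tests).
Note that median-of-ratios is *equivariant*, not invariant, under rescaling
one sample: scaling a sample by $c$ moves every size factor by the global
constant $c^{1/n}$ through the geometric-mean reference. Relative
expression is unaffected; the tests pin down exactly this behaviour.

Before network construction each gene is z-scored *within donor*
(`scale_within_batch`), which removes the donor's additive log-mean shift
and its variance multiplier — the two batch parameters the simulator
plants. Clustering (PCA → symmetrized kNN graph → Louvain with a resolution
parameter) and nearest-centroid annotation by Spearman correlation
(per-cluster, `min_corr` default 0.5) are deliberate simplifications of
anchor-based label transfer: adequate for well-separated types, not for
continuous gradients.

# Consensus module discovery

For one cell type with $n$ cells:

1. Pearson correlation on the donor-scaled matrix (biweight midcorrelation
   is out of scope; the per-donor scaling already tempers outliers).
2. Soft power $\beta$ chosen once on the full data as the smallest value in
   1..20 whose signed scale-free fit index reaches 0.8. The index is
   $-\mathrm{sign}(slope)\,R^2$ from regressing log-binned degree
   frequencies on log degree, so a decreasing (scale-free-like) degree
   distribution scores positive. A non-positive target disables the
   constraint. Signed-hybrid adjacency (negative correlations clipped to 0)
   is the default: module activity is later read as up/down-regulation of a
   coherent program, which an unsigned network would muddle.
3. `B_net` = 20 resamples of 80% of cells (without replacement, seeded);
   per resample correlation → adjacency (the *same* $\beta$) → TOM; the
   consensus TOM is the elementwise median. Fixing $\beta$ across resamples
   means consensus differences reflect sampling variability, not
   re-thresholding.
4. Average-linkage clustering on 1 − TOM with a *static* cut at the 0.99
   quantile of merge heights; clusters below `min_module_size` (10) become
   background. The static cut is a documented simplification of the dynamic
   hybrid tree cutter. Its cut point is calibrated by the shape of the
   merge-height distribution: with a realistic share of background genes
   most merges sit near height 1 and the 0.99 quantile lands just below
   them; a dataset composed almost entirely of module genes needs a lower
   quantile (the tests exercise such a case explicitly at 0.97).
5. Modules whose eigengenes (first PC of the standardized submatrix,
   unit-variance, sign-oriented toward the module mean) correlate above
   `merge_corr` = 0.85 are merged iteratively, highest pair first, ties by
   module order.
6. Quality control retains modules with ≥ 10 genes and mean gene–eigengene
   correlation (kME) ≥ 0.3.

Gene centrality is kIM — the within-module row sum of the consensus TOM —
not kME; kME is kept separately for QC. kIM is reported raw and normalized
to sum 1, and the normalized form is the weight of the activity statistic.

# Module activity and association

Activity of module $M$ in observation $j$ is
$\sum_{g \in M} w_g z_{gj}$ with $w$ the normalized kIM weights
(renormalized over the genes present in the target data) and $z$ the
gene's z-score across the target dataset's own observations. Pooling cases
and controls for the z-scoring is deliberate: the discovery and target
cohorts share no scale, so the target data must supply its own. Raw
activity therefore has mean 0 over the scaling population by construction;
a unit-variance standardization is used as the regression outcome so
coefficients are in SD-of-activity units.

Association fits ordinary least squares of standardized activity on the
numerically encoded grade (inflammation 0–2, fibrosis 0–1 — the encoding
mirrors how the grades enter the generative model) plus BMI, age and sex.
Inference is by case resampling: `B_assoc` = 1,999 bootstrap refits
(999 in the scaled validation runs), percentile 95% CI, and the two-sided
sign-count p-value
$p = 2\min(\#\{\beta^* \le 0\}+1, \#\{\beta^* \ge 0\}+1)/(B+1)$,
which is never exactly zero. Rank-deficient resamples are redrawn (error
if more than 10% must be). BH correction is applied across modules within
each phenotype. Steatosis is handled identically to inflammation; finding
no steatosis signal is a data outcome, not a pipeline difference.

# Preservation testing

A module is "preserved" in an external reference if its genes remain
co-expressed there. The statistic is the mean off-diagonal pairwise
correlation among module genes in the reference; the null is the same
statistic for `M_perm` (999; 199 in scaled runs) random size-matched gene
sets from the reference-expressed genes, so
$p \ge 1/(M_\mathrm{perm}+1)$; a Z score against the permutation null is
reported for comparability with composite preservation statistics, which
are out of scope. Modules with fewer than 5 genes present in the reference
are skipped with a logged reason, mirroring the omission of cell types
absent from a reference atlas.

A property worth knowing: on library-normalized counts the statistic is
*compositional*. Genes of two different strong modules are slightly
anti-correlated (when one program is up, the other's relative share drops),
so a null pool dominated by module genes sits slightly below the
independent-gene baseline. The synthetic preservation study therefore keeps
module genes at the same ~25% share of all genes as the discovery design;
at extreme module shares the size-matched null becomes mildly conservative
for destroyed modules.

# Enrichment

Candidate lists and GMT collections are tested per module with the exact
upper-tail hypergeometric probability (no normal approximation — the
interesting p-values are far in the tail), BH-corrected across modules
(candidates) or across retained sets (collections, size-filtered to 5–500
after universe intersection). The universe defaults to the genes that
entered module discovery for the cell type — the conservative choice, and
overridable; the universe size N is always reported. Module-overlap
structure uses the asymmetric shared-proportion matrix (entry = share of
the column module's genes found in the row module, diagonal fixed at 0,
rows/columns ordered by average-linkage clustering of the symmetrized
matrix), and `genes_in_at_least_k` extracts genes shared by at least k of
a chosen set of modules.

# The synthetic-data generator

The generator is the package's ground-truth instrument, not a fixture. Per
cell type, each planted module has a per-cell latent factor
$f \sim N(0, \sigma_f)$; gene log-means are
$\mathrm{base}_g + \lambda_g f + \mathrm{shift}_{donor} + N(0, \sigma_e)$
with loadings $\lambda_g \sim U(0.7, 1.3)$; counts are negative binomial
with log-normal library sizes and a donor-specific dispersion multiplier
(donor batch = additive log-mean shift + dispersion multiplier, exactly
what per-donor scaling must remove). Background genes carry no factor and
are independent given library size, keeping the false-module rate
interpretable. Defaults describe the scaled study design the package is
validated on: 10 donors × 200 cells, 600 genes, five 30-gene modules,
$\sigma_f = 2$, $\sigma_e = 0.3$, and a bulk cohort of 184 samples
(mirroring a 160-case/24-control design) with BMI ~ N(43.4, 7.4²) and age
~ N(44, 7.5²).

Two deliberate choices deserve a note:

* **Slope units.** Planted phenotype slopes are in SD-of-activity units, so
  the bulk generator budgets the latent activity's residual SD as
  $\sqrt{\max(0.05,\, 1 - \text{explained variance})}$; total activity SD
  is ≈ 1 and the planted slope lives on the same scale the regression
  estimates.
* **Destroyed modules in the reference.** A module not preserved in the
  reference keeps each gene's loading but attaches it to an *independent*
  per-gene factor (and copies of the loadings go to random background
  genes). This destroys all gene–gene correlation while preserving each
  gene's marginal variance; letting displaced loadings share a factor would
  merely relocate the co-expression, and stripping the variance instead
  makes destroyed genes the only low-variance genes in the data, which the
  compositional correlation structure would flag as (spuriously) preserved.

One emergent feature is worth understanding when reading results on
synthetic data: after library normalization the background genes share a
weak common component (minus the log total driven by the module factors),
so they form one large, genuinely co-expressed block that module detection
reports and preservation testing confirms. This is a real property of
compositional normalization, visible in real droplet data as well, and is
why recovered module counts are "planted + 1".

What the simulation does *not* emulate: zonation gradients, doublets,
ambient RNA, cell-cycle structure, or realistic cell-type abundance
profiles. Passing the synthetic validation shows the machinery is correct
and calibrated under the stated generative model; it does not certify
performance on data violating those assumptions.

# Numerical choices and degenerate inputs

* Correlation of zero-variance genes is defined as 0 (logged warning);
  their z-scores and scaled values are 0.
* TOM entries are clamped to [0,1] against floating-point overshoot and the
  matrix symmetrized; the diagonal is defined as 1.
* Eigengene orientation: flipped only when its correlation with the module
  mean is negative, so the rule is deterministic and idempotent.
* Merging ties break by module order; module ids are reassigned by
  decreasing size after QC, so output naming is stable.
* Bootstrap resamples with rank-deficient designs are redrawn and counted.
* Every stochastic stage takes its own integer seed from the configuration;
  `run_pipeline()` with a fixed configuration is byte-reproducible, and
  resolved configurations (with all seeds) are written alongside outputs.

# Validation scale

The bundled validation runs at: 2,000 cells / 600 genes / 5 modules for
consensus recovery (ARI ≥ 0.8 demanded, ≈ 0.99 observed); 184-sample bulk
cohorts with a 0.5 SD/grade planted slope for association (CI coverage and
sign recovery over 20 replicate cohorts; 200 null tests for type-I error);
20 modules (half preserved) over 2,400 genes for preservation
discrimination; and a three-module run of the full pipeline for
byte-identical determinism. These sizes keep the complete test suite at
roughly two minutes on one CPU while leaving every statistical property
measurable.

# Known limitations

* The static tree cut needs its quantile matched to the merge-height
  distribution; very unbalanced module/background compositions may require
  adjusting `cut_quantile`.
* The preservation statistic is a transparent surrogate (mean pairwise
  correlation vs size-matched sets), not a composite Zsummary; its null is
  mildly composition-sensitive as described above.
* Annotation is per-cluster nearest-centroid; per-cell transfer and
  anchor-based integration are out of scope.
* No blockwise approximation: networks are dense in memory, so the
  practical ceiling is roughly 10–20k genes per cell type.
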