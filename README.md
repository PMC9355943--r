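# coexmod

Cell-type-specific co-expression module discovery and phenotype association
for liver disease transcriptomics (and similar designs).

## The problem

In non-alcoholic steatohepatitis (NASH), disease processes play out in
particular liver cell types — stellate cells drive fibrosis, macrophage
subsets track inflammation, hepatocytes shed circulating markers. Single-cell
RNA-seq resolves the cell types but is usually available for only a handful
of donors, while histologically graded bulk RNA-seq cohorts are much larger.
`coexmod` implements the analysis strategy that joins the two:

1. **Robust WGCNA per cell type.** Within each cell type of a single-cell
   dataset, genes are clustered into co-expression modules via weighted gene
   co-expression network analysis: a Pearson correlation network is
   soft-thresholded (power chosen by the scale-free topology criterion,
   signed-hybrid by default), converted to a topological overlap matrix
   (TOM),

   TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij),

   and cut by average-linkage clustering on 1 − TOM. Robustness comes from a
   consensus: the TOM is recomputed on resampled subsets of cells and the
   elementwise median is clustered. Modules are merged by eigengene
   correlation and quality-filtered; each gene's centrality is its
   intramodular connectivity kIM (its summed TOM similarity to fellow
   members).

2. **Module activity projection.** A module's activity in any sample or cell
   is the kIM-weighted mean of the z-scored expression of its genes —
   a statistic that travels from the single-cell discovery data into an
   independent bulk cohort.

3. **Covariate-adjusted bootstrap association.** Module activity in the bulk
   cohort is regressed on ordinal histology grades (lobular inflammation
   0–2, fibrosis 0–1) controlling for BMI, age and sex; inference uses
   bootstrap percentile confidence intervals and sign-count p-values with
   Benjamini–Hochberg correction within each phenotype.

4. **Preservation testing.** Each module is tested for co-expression in an
   external (healthy) single-cell reference against size-matched random gene
   sets (permutation p, BH-corrected).

5. **Hypergeometric mapping.** Candidate gene lists (e.g. GWAS effector
   genes) and GMT gene-set collections are mapped onto modules by exact
   upper-tail hypergeometric tests.

Because raw patient-level single-cell data of this kind are typically not
public, the package ships a first-class synthetic-data generator that plants
known modules, donor batch effects, preservation structure and
phenotype–activity slopes, so every stage of the pipeline is verifiable
against ground truth.

## Worked example

```r
library(coexmod)

cfg  <- sim_config(seed = 1)        # 10 donors x 200 cells, 600 genes,
                                    # 5 planted modules of 30 genes
sc   <- simulate_sc_dataset(cfg)
scaled <- scale_within_batch(normalize_log(qc_filter_cells(sc$expr)))

net  <- consensus_modules(scaled, pipeline_config(), cell_type = "CT1")
net$module_set
#> ModuleSet: 6 modules, 1 background genes
#>   M-CT1-1: 449 genes
#>   M-CT1-2: 30 genes
#>   M-CT1-3: 30 genes
#>   M-CT1-4: 30 genes
#>   M-CT1-5: 30 genes
#>   M-CT1-6: 30 genes

labs <- module_recovery_labels(sc$truth, net$module_set)
adjusted_rand_index(labs$truth_labels, labs$found_labels)
#> [1] 0.9948938
```

All five planted 30-gene modules are recovered exactly; the sixth "module"
is the block of background genes that co-vary through the shared
library-size normalization (see the vignette). Projecting into a simulated
bulk cohort and testing association:

```r
bulk <- simulate_bulk_dataset(cfg, sc$truth)
norm <- normalize_median_of_ratios(bulk$expr)
act  <- activity_matrix(norm$expr, net$module_set)
associate_modules(act, bulk$meta, B_assoc = 999, seed = 1)
#>   module            phenotype     beta  ci_low ci_high p_boot   n p_adj
#>  M-CT1-2 lobular_inflammation  0.43648  0.2815  0.5947  0.002 184 0.012
#>  M-CT1-3 lobular_inflammation -0.24608 -0.4301 -0.0676  0.010 184 0.030
#>  M-CT1-3             fibrosis  0.56133  0.2799  0.8421  0.002 184 0.012
#>  ...                                              (9 further rows, ns)
```

The module carrying the planted inflammation program (0.5 SD of activity
per grade; recovered as M-CT1-2) is flagged with a positive effect whose
95% bootstrap CI covers the truth, and the planted fibrosis module
(M-CT1-3) likewise. M-CT1-3's small negative inflammation coefficient is
compositional spillover from library normalization — discussed in the
vignette.

A thin command-line wrapper with `simulate`, `preprocess`, `modules`,
`associate`, `enrich` and `run-all` subcommands lives at
`inst/cli/coexmod.R`:

```sh
Rscript inst/cli/coexmod.R run-all --config inst/extdata/synthetic_config.txt \
    --out-dir out/
```

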