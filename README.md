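# iqtlkit

Immune infiltration scoring and infiltration-QTL (iQTL) association
analysis for bulk expression cohorts, with a synthetic-data module that
makes the whole pipeline testable end to end without any external data.

Bulk RNA-seq profiles are mixtures of cell types, and the amount of
infiltrating immune cells in a tissue varies widely between donors. This
package is for analysts who want to quantify that immune content per
sample, define tissue-by-cell-type *infiltration phenotypes*, and scan
them for demographic (age, sex) and germline genetic associations —
treating variants associated with an infiltration phenotype as iQTLs —
then characterize the hits (immune-hot/cold sample structure, overlap with
eQTLs and prior GWAS associations).

## What it computes

* **Three cell-type scores per sample**, used in parallel throughout:
  *relative* fractions from non-negative least squares on a marker-gene
  signature (composition of the immune compartment, rows sum to 1);
  *absolute* scores = relative × a per-sample scaling factor
  (median expression over signature genes / median over all genes);
  *enrichment* scores from a rank-based weighted running-sum statistic per
  marker set, batched within one tissue. A permutation *presence P-value*
  tests whether any reference immune signal is present at all.
* **Phenotype filtering** by five criteria (N > 70; >50% of samples with
  presence P < 0.50; mean relative > 5% and mean enrichment > 0.001;
  non-negative absolute/enrichment correlation; no cell lines).
* **Association scans** — multiple regression for age/sex; covariate
  residualization + rank-inverse normal transform + per-SNP simple
  regression for the genome-wide scan after MAF/missingness/HWE QC — with
  the three per-method P-values merged by **Empirical Brown's method**:
  with w_i = −2·log(ecdf_i(x_i)) per method, X = −2·Σ log p_i is referred
  to a chi-square with f = 2E²/Var degrees of freedom scaled by
  c = Var/(2E), where E = 2k and Var = 4k + 2·Σ_{i<j} cov(w_i, w_j).
  Tiers: P < 5×10⁻⁸ genome-wide, P < 10⁻⁵ suggested, BH-FDR < 0.1.
* **Hot/cold detection** by consensus k-means (resampled co-clustering,
  model selection by the maximum relative change in the consensus-CDF
  area) and by quintile membership across all three methods, plus a
  Bonferroni-corrected Fisher test of hot-pattern independence between
  tissues.
* **Enrichment tests**: observed iQTL/eQTL overlap x in N iQTLs against a
  null proportion q from 100 permutations drawing MAF- and LD-matched
  variants, with an exact binomial tail P(X ≥ x | N, q); N-weighted
  pooling across phenotypes; an unmatched GWAS-catalog fold-enrichment
  test.
* **Synthetic cohorts** with planted age/sex/SNP effects, block-LD
  genotypes, spike-in mixture panels and flagged variant annotations, so
  every claim above is checked against known truth.

## Worked example

The `analysis/` directory is the package's own study, run in order:

```sh
Rscript analysis/01_simulate.R                 # cohort + spike-in panel
Rscript analysis/02_deconvolution_evaluation.R # scorer evaluation
Rscript analysis/03_phenotypes.R               # scoring, filtering, PCs
Rscript analysis/04_age_sex.R                  # demographic associations
Rscript analysis/05_gwas.R                     # genome-wide iQTL scan
Rscript analysis/06_hotcold.R                  # hot/cold clustering
Rscript analysis/07_enrichment.R               # eQTL / catalog enrichment
Rscript analysis/08_power_fpr.R                # power & FPR of the EBM
```

Stage 2 prints the scorer evaluation on the 40-mix spike-in panel:

```
     method cell_type pearson_r.tissue pearson_r.immune
   relative     CD4_T        0.8091666        0.9974782
   relative     CD8_T        0.7615303        0.9968602
   absolute     CD4_T        0.9741892        0.8358181
   absolute     CD8_T        0.9532721        0.7325842
 enrichment     CD4_T        0.9782509        0.8505306
 enrichment     CD8_T        0.9350685        0.8269942
Relative beats absolute under the immune-cell truth (CD4: 0.997 vs 0.836);
the ordering reverses under the tissue truth (0.809 vs 0.974).
```

i.e. relative scores recover the *composition* of the immune compartment
almost exactly, while absolute and enrichment scores track the *amount* of
each cell type in the whole sample — the reason all three are carried
forward and combined rather than picking one.

Stage 5 recovers the planted genetic effect (rs000100 → CD8 T cells,
logit effect 0.8) as the top combined-P hit in both tissues:

```
 phenotype_id variant_id   combined_p
  colon:CD8_T   rs000100 5.973596e-38
   skin:CD8_T   rs000100 2.497492e-36
```

and stage 8 shows the point of combining dependent P-values:

```
 beta rate_m1 rate_m2 rate_m3 rate_combined
  0.0   0.028   0.048   0.040         0.038
  0.4   0.730   0.726   0.706         0.812
  0.6   0.976   0.970   0.980         0.992
```

— higher detection rates than any single method at every planted effect,
at a preserved false positive rate (the beta = 0 row).

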