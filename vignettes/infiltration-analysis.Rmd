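---
title: "Methods: immune infiltration scoring and infiltration-QTL analysis"
author: "iqtlkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune infiltration scoring and infiltration-QTL analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iqtlkit)
```

## The problem

Bulk RNA-seq measures a mixture: an expression profile of a tissue sample
is a weighted sum of the profiles of the cell types it contains, including
infiltrating immune cells. This package implements a complete analysis
chain for asking what drives the variability of that immune content across
donors: per-sample cell-type scoring by three complementary methods,
definition and filtering of tissue-by-cell-type *infiltration phenotypes*,
association scans against demographic covariates and genome-wide genotypes
with a dependent-P-value combination, detection of immune-hot and
immune-cold samples, and permutation-matched enrichment tests of the
resulting infiltration QTLs (iQTLs) against variant annotations.

Because the cohort data such analyses normally run on are access-controlled,
the package ships a synthetic-data module that generates every input with
known ground truth — cohorts, genotypes with block LD, marker-gene
signatures, expression mixtures, spike-in panels, variant annotations — so
that every downstream stage is testable end to end.

## Cell-type scoring

Three scores are computed per sample and cell type, deliberately echoing
the two families of published estimators (mixture deconvolution and
single-sample gene-set enrichment) in simplified, fully specified form:

* **Relative scores** solve a non-negative least-squares problem restricted
  to the signature genes, `min ||S w − x||` with `w ≥ 0`, and renormalize
  `w` to sum to 1. They estimate the composition of the immune compartment:
  fractions of the immune content, not of the sample. The solver is an
  in-package Lawson–Hanson active-set iteration on the normal equations;
  with the small signature matrices used here each call reduces to a few
  tiny linear solves, which is what makes the permutation presence test
  affordable at its default 1000 permutations. An optional
  nu-support-vector-regression mode (via e1071) sits behind the same
  contract.
* **Absolute scores** multiply the relative fractions by a per-sample
  *scaling factor* measuring total immune content. The factor is defined
  here as the median expression over signature genes divided by the median
  over all genes. That formula is a package design choice — the published
  analogue is defined only through its multiplicative role — and its
  contract is behavioral: on spiked mixtures the factor must be monotone in
  the true total immune fraction, which the test suite asserts across every
  spike design series.
* **Enrichment scores** rank each sample's genes by decreasing expression
  and score each cell type's marker set with a weighted running-sum
  statistic (hit weight `(N − rank + 1)^0.25`, miss weight uniform), taking
  the maximum deviation of the hit curve over the miss curve and flooring
  at zero. A set occupying the top ranks scores exactly 1. Scores are
  comparable only within a single-tissue batch — cross-tissue batches
  change what "high rank" means — so the scorer refuses mixed batches.
  No spillover compensation between related cell types is attempted.

The **presence P-value** tests the null that no reference immune cells are
present: the statistic is the correlation between the NNLS reconstruction
and the observed profile over signature genes, and the null distribution
comes from shuffling gene labels and refitting, with
`P = (1 + #{permuted ≥ observed}) / (n_perm + 1)`.

On spike-in panels (four design types — CD4 only, CD8 only, equal, and
2:3 / 1:4 unequal mixtures — at 5–20% total immune content, with
homogeneous and heterogeneous reference variants), the two score families
specialize exactly as their constructions suggest: relative scores
correlate best with the *immune-compartment* truth (r ≈ 1.0 here) and
absolute scores with the *whole-sample* truth (r ≈ 0.97 vs 0.81 for
relative). This asymmetry is the reason the pipeline carries all three
scores forward in parallel rather than choosing one.

## Infiltration phenotypes and filtering

Raw subtype scores are merged into analysis cell types by summation; the
specific types partition the subtypes disjointly (so totals are conserved),
while composite types (lymphoid, myeloid, the CD4 composite) may overlap
them. No renormalization is applied after merging — sums, not re-scaled
fractions, are carried forward, so that the absolute/relative relationship
survives merging.

One candidate phenotype exists per (tissue, cell type) pair — 16 cell
types in 46 tissues would give 736 — and a phenotype is kept only if all
five criteria hold, with boundaries strict as stated:

1. tissue sample size `N > 70` (N = 70 fails);
2. more than 50% of the tissue's samples have relative-method presence
   `P < 0.50`;
3. the cell type is substantial: mean relative score > 0.05 and mean
   enrichment score > 0.001;
4. absolute and enrichment scores correlate non-negatively (exactly 0
   passes; an undefined correlation from a constant score vector is
   treated as a failure, since agreement cannot be established);
5. the tissue is not an excluded (cell-line) tissue.

The filter is order-independent and idempotent, and the audit table records
every criterion's value and the first failure per phenotype.

Ratio phenotypes (e.g. CD4:CD8) add `ε = 1e-10` to numerator and
denominator — zero-over-zero becomes 1 rather than undefined — and then
apply the rank-based inverse normal transform. The transform uses offset
0.5, `z = Φ⁻¹((rank − 0.5)/n)`, with average ranks on ties; the offset is
a design choice (the convention is not fixed by the procedure being
mirrored). A constant vector carries no rank information and is rejected
rather than silently mapped to zeros. Since the absolute score is the
relative score times a sample-level factor, absolute and relative ratios
are identical; ratio phenotypes therefore combine only two methods
(relative and enrichment) with a 2×2 covariance.

Expression principal components are computed per tissue on the
gene-centered and, by default, unit-variance-scaled matrix ("processed" is
otherwise underdetermined; the scaling policy is recorded in the call).
Each phenotype's absolute scores are regressed on each of the first four
components, with BH-FDR across all (phenotype, PC) pairs at level 0.1.

## Association scans and Empirical Brown's method

Genotype QC removes variants with MAF < 0.05, missingness > 0.1, or
Hardy–Weinberg `P < 1e-6` (1-df chi-square without continuity correction
from non-missing genotype counts; the exact test is not needed at a 1e-6
threshold). Genotype principal components come from an SVD of the
centered, variance-standardized, mean-imputed dosage matrix; three enter
the covariate model. Expression-derived latent factors are deliberately
*not* covariates: they correlate strongly with the infiltration scores
themselves and would absorb the signal under study.

For the genome-wide scan each phenotype is residualized against the full
covariate design (age bin numeric, sex, death classification, autolysis,
collection site, genotype PCs), the residuals are rank-inverse-normal
transformed, and the transformed vector is regressed on each variant's
dosage with pairwise deletion of missing genotypes (slope, SE, two-sided
t-test; a t rather than z reference, the difference being negligible at
these sample sizes). Age and sex effects are instead read directly off the
full multiple regression on raw scores, with no prior residualization.

The three per-method P-values for each term are combined with **Empirical
Brown's method**, the dependent-data extension of Fisher's combination.
Each method's score vector is standardized and pushed through its own
right-continuous empirical CDF, `w_i(s) = −2·log(ecdf_i(x_i(s)))`, with
the ECDF floored at `1/N` so no logarithm of zero occurs (the floor is a
convention choice of this implementation). With `E = 2k` and
`Var = 4k + 2·Σ_{i<j} cov(w_i, w_j)`, Fisher's statistic
`X = −2·Σ log p_i` is referred to a chi-square with `f = 2E²/Var` degrees
of freedom after scaling by `c = Var/(2E)`. Zero covariance recovers
Fisher's method exactly; three perfectly correlated methods recover the
shared single P up to finite-N error. A negative estimated `Var` (possible
under strong negative covariance) falls back to the independence value
`4k` with a warning; legitimately small positive variances from
anti-correlated methods are kept. Because only ranks enter the ECDF, the
combination is invariant to increasing affine rescaling of any score
vector.

Significance tiers are strict: genome-wide at combined `P < 5e-8`,
suggested at `P < 1e-5`, and FDR-based calls at BH-adjusted `P < 0.1`
(age- and sex-P-values adjusted separately). Suggested-tier counts are
raw per-SNP, with no LD de-duplication.

## Hot and cold samples

Consensus k-means runs on each phenotype's score vector per method. The
1×N vector is cloned into three identical rows before clustering — a
literal reproduction of the procedure being mirrored; it is mathematically
a rescaling of Euclidean distances. Each resampling cycle subsamples 80%
of samples without replacement (the subsample fraction is a package
default; it is configurable) and k-means (10 restarts by default) labels
the subsample; consensus entries are co-clustering counts normalized by
co-sampling counts. Model selection integrates the consensus CDF
`CDF(c) = Σ_{i<j} 1{M(i,j) ≤ c} / (N(N−1)/2)` over a threshold grid and
picks the k with the maximum relative change in area between consecutive
k (the area itself for the smallest k), ties toward smaller k. The
maximum-mean cluster is hot, the minimum-mean cluster cold, everything
else intermediate; exact mean ties break toward the smaller cluster index.
Quintile labels use nearest-rank cuts — top and bottom `q = 0.2` (or 0.4,
relaxed) in *all three* methods — sized so that distinct scores give
exactly `floor(q·n)` samples per side. Consensus hot/cold sets are the
intersection across methods.

The hot-sharing test asks, per cell type and tissue pair, whether being
hot in one tissue is independent of being hot in the other: a 2×2 Fisher
exact test (two-sided by default; sidedness is a switch) over the donors
sampled in both tissues, Bonferroni-corrected at 0.05 over the number of
pairs tested. Tables with a zero margin are logged with P = 1. Per-donor
hot burden (count, fraction, and mode of hot tissues) is restricted to
donors with at least eight sampled tissues by default. Differential
expression between hot and cold clusters is out of scope; the module
exports the label sets such an analysis would consume.

## Enrichment of iQTLs in annotations

The eQTL enrichment test controls for the two properties that make a
variant a priori likely to be an eQTL — allele frequency and LD — by
matching: each iQTL's candidate pool contains variants with MAF within
0.01 and an identical LD-partner count (r² > 0.2 partners), relaxed to ±1
when the exact count yields nothing; a pool still empty after the full
schedule is an explicit error rather than a silently widened match. One
hundred permutations draw one matched variant per iQTL (uniformly, with
replacement across permutations) and the mean flagged proportion across
permutations is the null `q` for an exact one-sided binomial test of the
observed overlap `x` in `N` iQTLs. Phenotype-level results pool with an
N-weighted `q_new = Σ N_p q_p / Σ N_p`. The GWAS-catalog test is
deliberately *unmatched* — iterations draw uniform genome-wide sets of the
same size, mirroring the asymmetry of the procedure being reproduced —
and reports the fold change of observed over expected proportion. Binomial
tails are computed by direct summation (two-sided by the
minimum-likelihood rule), never by normal approximation, so printed values
are reproduced by rounding only.

The matched null is not decoration: with eQTL flags planted to favor
common variants and iQTLs drawn from the high-MAF tail, the unmatched test
inflates its false-rejection rate severalfold while the matched test stays
near the nominal level — the test suite asserts exactly this contrast.

## The synthetic cohort generator

The generator is the package's study design, not a tuning knob; its
defaults are fixed once:

* **Cohort**: donors carry age bins (multiples of 10), sex (F/M at 0.5),
  death class 0–4, a continuous autolysis score, and a collection site;
  each donor contributes a sample per tissue with a configurable
  sampling rate.
* **Genotypes**: block-copy LD — within a block each variant copies the
  previous variant's haplotypes, resampling each with probability
  `recomb_prob` — gives tunable, decaying r² structure with evenly spaced
  integer positions; missingness is uniform at random. All per-variant
  metadata (MAF, missingness, HWE P, LD partner count at r² > 0.2) are
  recomputed from the emitted matrix, never copied from generator inputs;
  LD counts use mean-imputed correlations so the whole computation is one
  matrix product.
* **Fractions**: cell-type fractions follow an inverse-logit linear model
  in standardized covariates (age, sex, target-SNP dosage) plus Gaussian
  logit noise, rescaled per sample so the total stays below a cap (0.6 by
  default, ~4% baseline per subtype). A logit-linear model is the
  simplest generative mechanism with controllable, sign-correct planted
  effects; nothing in the analyzed procedure prescribes one.
* **Expression**: linear expression-level mixing
  `x = (1 − Σf)·background + Σ f_c·profile_c` with unit-mean lognormal
  noise (CV 0.15 by default). Mixing happens at the profile level, not the
  read level: the compositional ground truth the evaluation needs is
  preserved, and no sequence data are required.
* **Signatures**: each cell type owns a disjoint set of marker genes
  boosted ~30-fold in its pure profile and suppressed in tissue
  backgrounds.
* **Annotations**: eQTL flags drawn at a base rate with an optional
  log-odds slope on centered MAF (the plantable confounder above);
  catalog flags independent.

What the generator does **not** emulate — and therefore what passing tests
do not certify about real data — includes count-model overdispersion and
GC/length bias, population structure and admixture, spillover between
transcriptionally close cell types, differential (non-random) genotype
missingness, and read-level artifacts. Conclusions from the synthetic
study are about the statistical machinery, not about any particular real
cohort.

## Numerical choices and problem sizes

Tolerances and tie-breaks that matter: relative score rows sum to 1 within
1e-9; NNLS dual-feasibility tolerance scales with machine epsilon and the
normal-equation magnitude; MAF matching applies a 1e-12 slack so the
printed 0.01 tolerance is inclusive under binary floating point; quantile
and cluster-mean ties resolve deterministically (nearest rank; smallest
cluster index); degenerate Fisher tables return P = 1 and are flagged; a
constant vector is an error, not a zero, wherever ranks are needed.
Combined P-values are clamped into (0, 1].

The shipped analysis runs at desk scale, chosen so the full workflow and
test suite complete in minutes on one core: 150 donors × 2 tissues (300 in
the end-to-end recovery study, which uses an independent-variant panel so
that "top hit" identifies the causal variant rather than an LD tag), 400
variants in blocks of 8, 600 genes with 20 markers per cell type, 1000
presence permutations in the main analysis with smaller budgets in
repeated-run studies, consensus clustering at 200 resampling cycles over
k = 2..6 in the analysis scripts (the function defaults remain 2000 cycles
over k = 2..20), 100 matched permutations, and 2000 simulated tests for
the null-calibration checks. Statistical thresholds are never scaled:
5e-8, 1e-5, FDR 0.1, the five filter criteria, ε = 1e-10, MAF tolerance
0.01 and the ±1 LD relaxation are used exactly as stated everywhere.

## Known limitations

The scorers are intentionally simplified stand-ins for the published
estimator families: no ν-SVR feature selection, no spillover compensation,
no reference-panel curation. The scaling factor is behaviorally, not
formulaically, anchored. The hot-sharing test conditions on observed hot
labels rather than propagating clustering uncertainty. The EBM covariance
is estimated from the same vectors being tested, which is exactly the
cited method's design but means very short score vectors (N below ~20)
give noisy degrees-of-freedom estimates. LD-partner counts computed from
small synthetic panels are self-consistent but not comparable to counts
from external reference panels.
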