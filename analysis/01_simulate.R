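#!/usr/bin/env Rscript
# Stage 1 -- simulate the study inputs.
#
# Builds the synthetic cohort the rest of the analysis runs on: 150 donors
# sampled in two tissues, 400 variants in LD blocks, a marker-gene
# signature over 600 genes, planted age / sex / SNP effects on cell-type
# fractions, bulk expression mixed from the planted fractions, and a
# variant annotation with eQTL and GWAS-catalog flags. Also emits the
# immune-spiked mixture panel (four design types, 5-20% total immune
# content) used to evaluate the scorers in stage 2.
#
# Everything downstream reads these files from results/data/.

library(iqtlkit)

seed <- 20260921L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- generate_cohort(150, c("colon", "skin"), seed = stage_seed(seed, "cohort"))
genotypes <- generate_genotypes(cohort, 400, maf_range = c(0.1, 0.5),
                                block_size = 8, recomb_prob = 0.15,
                                missing_rate = 0.02,
                                seed = stage_seed(seed, "genotypes"))
signature <- make_signature(unique(default_subtype_map()$raw),
                            c("colon", "skin"), n_genes = 600,
                            n_markers = 20,
                            seed = stage_seed(seed, "signature"))

# planted truth: age raises macrophages, sex (F) raises B cells, and
# rs000100 raises CD8 T cells
spec <- data.frame(cell_type = unique(default_subtype_map()$raw),
                   base = 0.04, beta_age = 0, beta_sex = 0, beta_snp = 0,
                   snp_id = NA_character_)
spec$beta_age[spec$cell_type == "Macrophage"] <- 0.5
spec$beta_sex[spec$cell_type == "B"] <- 0.6
spec$beta_snp[spec$cell_type == "CD8_T"] <- 0.8
spec$snp_id[spec$cell_type == "CD8_T"] <- "rs000100"

design <- plant_effects(cohort, genotypes, spec, noise_sd = 0.4,
                        total_cap = 0.6, seed = stage_seed(seed, "effects"))
expr <- synthesize_expression(design, signature, noise_cv = 0.15,
                              seed = stage_seed(seed, "expression"))
annotation <- generate_annotation(genotypes, c("colon", "skin"),
                                  base_rate = 0.15, catalog_rate = 0.05,
                                  seed = stage_seed(seed, "annotation"))

write_covariates_tsv(cohort$donors, file.path(out, "donors.tsv"))
write_covariates_tsv(cohort$samples, file.path(out, "samples.tsv"))
write_dosage_tsv(genotypes, file.path(out, "genotypes.tsv"))
write_vcf(genotypes, file.path(out, "genotypes.vcf"))
write_gct(expr, file.path(out, "expression.gct"))
write_gmt(signature$gene_sets, file.path(out, "gene_sets.gmt"))
write_annotation_tsv(annotation, file.path(out, "annotation.tsv"))
write_covariates_tsv(spec, file.path(out, "planted_effects.tsv"))

# spike-in panel on the colon background, five reference profiles per type
set.seed(stage_seed(seed, "spike_refs"))
jitter_profiles <- function(ct) {
  p <- sapply(1:5, function(i)
    signature$profiles[, ct] * rlnorm(nrow(signature$profiles), 0, 0.2))
  rownames(p) <- rownames(signature$profiles)
  p
}
sp <- spike_series(signature$background[, "colon"],
                   jitter_profiles("CD4_naive"), jitter_profiles("CD8_T"),
                   seed = stage_seed(seed, "spike"))
write_expression_tsv(sp$expression, file.path(out, "spike_expression.tsv"))
write_covariates_tsv(cbind(sp$design$samples,
                           true_cd4 = sp$design$tissue_frac[, "CD4_T"],
                           true_cd8 = sp$design$tissue_frac[, "CD8_T"]),
                     file.path(out, "spike_truth.tsv"))

cat("Simulated", nrow(cohort$samples), "samples,",
    ncol(genotypes$dosage), "variants,",
    nrow(expr), "genes;", ncol(sp$expression), "spike-in mixes.\n")
cat("Planted effects: age->Macrophage (0.5), sex->B (0.6),",
    "rs000100->CD8_T (0.8) on the logit scale.\n")
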