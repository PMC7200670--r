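#!/usr/bin/env Rscript
# Stage 5 -- genome-wide iQTL scan.
#
# QC-filters the variants (MAF < 0.05, missingness > 0.1, HWE P < 1e-6),
# residualizes each kept phenotype against the covariates plus three
# genotype principal components, rank-inverse-normal transforms the
# residuals, regresses them on every variant per scoring method, and
# combines the three per-SNP P-values with Empirical Brown's method
# (covariance from the transformed residual phenotypes). Hits are tiered
# at P < 5e-8 (genome-wide) and P < 1e-5 (suggested).

library(iqtlkit)

donors <- read_covariates_tsv("results/data/donors.tsv")
samples <- read_covariates_tsv("results/data/samples.tsv")
genotypes <- read_dosage_tsv("results/data/genotypes.tsv")
merged <- lapply(c(relative = "relative", absolute = "absolute",
                   enrichment = "enrichment"),
                 function(m) read_scores_tsv(sprintf("results/scores_%s.tsv", m)))

qc <- qc_genotypes(genotypes)
cat("QC removed", nrow(qc$removed), "of", ncol(genotypes$dosage),
    "variants:", paste(capture.output(print(table(qc$removed$reason))),
                       collapse = " "), "\n")
pcs <- genotype_pcs(qc$genotypes$dosage, 3)

phens <- build_phenotypes(merged$relative, merged$absolute,
                          merged$enrichment)
filt <- filter_phenotypes(phens, filter_criteria())

rows <- list()
for (ph in filt$kept) {
  dids <- samples$donor_id[match(ph$sample_ids, samples$sample_id)]
  cv <- donors[match(dids, donors$donor_id), ]
  X <- covariate_design(cv, pcs[dids, , drop = FALSE])
  zs <- lapply(ph$scores, function(y)
    setNames(adjust_and_transform(y, X), dids))
  scans <- lapply(zs, snp_scan, genotypes = qc$genotypes)
  cov_sum <- ebm_covsum(do.call(rbind, zs))
  pm <- cbind(scans$relative$p, scans$absolute$p, scans$enrichment$p)
  comb <- apply(pm, 1, function(p3)
    if (anyNA(p3)) NA_real_ else brown_combine(p3, cov_sum))
  rows[[length(rows) + 1]] <- data.frame(
    phenotype_id = paste(ph$tissue, ph$cell_type, sep = ":"),
    variant_id = scans$relative$variant_id, n = scans$relative$n,
    p_relative = pm[, 1], p_absolute = pm[, 2], p_enrichment = pm[, 3],
    combined_p = comb)
}
gwas <- do.call(rbind, rows)
gwas <- significance_calls(gwas)
write.table(gwas, "results/gwas.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

gw <- gwas[gwas$genome_wide, ]
cat(length(unique(gw$phenotype_id)), "phenotypes with a genome-wide",
    "significant iQTL (P < 5e-8);", sum(gwas$suggested),
    "suggested associations (P < 1e-5).\n")
top <- gw[order(gw$combined_p), ][1:min(5, nrow(gw)),
                                  c("phenotype_id", "variant_id",
                                    "combined_p")]
print(top, row.names = FALSE)
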