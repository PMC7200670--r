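#!/usr/bin/env Rscript
# Stage 4 -- demographic associations.
#
# Fits the full multiple regression (age bin, sex, death class, autolysis,
# site) to each kept phenotype's scores separately per scoring method and
# combines the three age P-values -- and, separately, the three sex
# P-values -- with Empirical Brown's method using the 3x3 empirical
# covariance of the method score vectors. BH-FDR is applied per term.
# Also runs the CD4:CD8 ratio phenotype in each tissue with the epsilon
# offset and rank-inverse normal transform, combining relative and
# enrichment methods with a 2x2 covariance (the absolute ratio equals the
# relative ratio, so it carries no extra information).

library(iqtlkit)

donors <- read_covariates_tsv("results/data/donors.tsv")
samples <- read_covariates_tsv("results/data/samples.tsv")
merged <- lapply(c(relative = "relative", absolute = "absolute",
                   enrichment = "enrichment"),
                 function(m) read_scores_tsv(sprintf("results/scores_%s.tsv", m)))

phens <- build_phenotypes(merged$relative, merged$absolute,
                          merged$enrichment)
filt <- filter_phenotypes(phens, filter_criteria())

cov_of <- function(ids) {
  donors[match(samples$donor_id[match(ids, samples$sample_id)],
               donors$donor_id), ]
}

rows <- list()
for (ph in filt$kept) {
  cv <- cov_of(ph$sample_ids)
  fits <- lapply(ph$scores, age_sex_scan, covariates = cv)
  smat <- do.call(rbind, ph$scores)
  for (term in c("age", "sex")) {
    ps <- vapply(fits, function(f) f$p[f$term == term], numeric(1))
    rows[[length(rows) + 1]] <- data.frame(
      phenotype_id = paste(ph$tissue, ph$cell_type, sep = ":"),
      term = term, n = ph$n, p_relative = ps["relative"],
      p_absolute = ps["absolute"], p_enrichment = ps["enrichment"],
      combined_p = ebm_combine(ps, smat))
  }
}
res <- do.call(rbind, rows)
res$fdr <- NA_real_
for (term in c("age", "sex"))
  res$fdr[res$term == term] <- bh_fdr(res$combined_p[res$term == term])
res$fdr_significant <- res$fdr < 0.1
write.table(res, "results/age_sex.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sig <- res[res$fdr_significant, ]
cat(length(unique(sig$phenotype_id)), "of",
    length(unique(res$phenotype_id)),
    "phenotypes associated with age or sex at FDR < 0.1:\n")
print(sig[order(sig$combined_p),
          c("phenotype_id", "term", "combined_p", "fdr")],
      row.names = FALSE)

# CD4:CD8 ratio phenotypes (2x2 EBM)
ratio_rows <- list()
for (tis in unique(samples$tissue)) {
  ids <- intersect(samples$sample_id[samples$tissue == tis],
                   rownames(merged$relative$scores))
  cv <- cov_of(ids)
  ps <- numeric(0)
  smat <- NULL
  for (m in c("relative", "enrichment")) {
    ratio <- ratio_phenotype(merged[[m]]$scores[ids, "CD4_T"],
                             merged[[m]]$scores[ids, "CD8_T"])
    fit <- age_sex_scan(ratio, cv)
    ps <- c(ps, fit$p[fit$term == "age"])
    smat <- rbind(smat, ratio)
  }
  ratio_rows[[tis]] <- data.frame(
    phenotype_id = paste0(tis, ":CD4_CD8_ratio"), term = "age",
    n = length(ids), combined_p = ebm_combine(ps, smat))
}
ratio_res <- do.call(rbind, ratio_rows)
write.table(ratio_res, "results/age_sex_ratio.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("CD4:CD8 ratio age associations (2x2 EBM):\n")
print(ratio_res, row.names = FALSE)
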