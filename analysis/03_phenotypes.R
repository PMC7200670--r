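#!/usr/bin/env Rscript
# Stage 3 -- score the cohort and define infiltration phenotypes.
#
# Scores every cohort sample with the three methods (the relative scorer
# also carries the 1000-permutation presence test), merges the seven raw
# subtypes into six specific cell types plus the lymphoid/myeloid
# composites, enumerates one phenotype per (tissue, cell type), applies
# the five-criterion filter, and regresses each kept phenotype's absolute
# scores on the first four expression principal components per tissue.

library(iqtlkit)

seed <- 20260921L
signature <- make_signature(unique(default_subtype_map()$raw),
                            c("colon", "skin"), n_genes = 600,
                            n_markers = 20,
                            seed = stage_seed(seed, "signature"))
expr <- read_gct("results/data/expression.gct")
samples <- read_covariates_tsv("results/data/samples.tsv")
tissues <- setNames(samples$tissue, samples$sample_id)[colnames(expr)]

rel <- deconvolve(expr, signature, tissues, "relative", presence = TRUE,
                  n_perm = 1000, seed = stage_seed(seed, "presence"))
abs_ <- score_absolute(rel, rel$scaling_factor)
enr <- deconvolve(expr, signature, tissues, "enrichment")

map <- default_subtype_map()
merged <- lapply(list(relative = rel, absolute = abs_, enrichment = enr),
                 merge_subtypes, map = map)
for (m in names(merged))
  write_scores_tsv(merged[[m]], sprintf("results/scores_%s.tsv", m))

phens <- build_phenotypes(merged$relative, merged$absolute,
                          merged$enrichment)
filt <- filter_phenotypes(phens, filter_criteria())
write.table(filt$audit, "results/phenotype_audit.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(length(phens), "candidate phenotypes (",
    length(unique(vapply(phens, `[[`, character(1), "cell_type"))),
    "cell types x 2 tissues );", length(filt$kept), "kept by the filter.\n")

# expression PCs vs absolute scores, per tissue
pc_rows <- list()
for (tis in unique(tissues)) {
  ids <- names(tissues)[tissues == tis]
  kept_here <- Filter(function(p) p$tissue == tis, filt$kept)
  if (!length(kept_here)) next
  phen_mat <- sapply(kept_here, function(p) p$scores$absolute[ids])
  colnames(phen_mat) <- vapply(kept_here, function(p)
    paste(p$tissue, p$cell_type, sep = ":"), character(1))
  pc_rows[[tis]] <- pc_phenotype_scan(expr[, ids], phen_mat, n_pcs = 4)
}
pc_res <- do.call(rbind, pc_rows)
pc_res$fdr <- bh_fdr(pc_res$p)          # re-adjust across all tissues
pc_res$significant <- pc_res$fdr < 0.1
write.table(pc_res, "results/pc_phenotype_scan.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
n_sig <- length(unique(pc_res$phenotype[pc_res$significant]))
cat(n_sig, "of", length(unique(pc_res$phenotype)),
    "kept phenotypes correlate with an expression PC at FDR < 0.1.\n")
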