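#!/usr/bin/env Rscript
# Stage 7 -- annotation enrichment of the iQTL results.
#
# Takes the suggested iQTLs (combined P < 1e-5) per phenotype, matches
# every iQTL to variants of similar MAF (within 0.01) and LD partner
# count (exact, then +/- 1), builds a 100-permutation null for the
# same-tissue eQTL overlap, and tests the observed overlap with the exact
# one-sided binomial test; phenotype-level results are pooled with an
# N-weighted null. The GWAS-catalog test draws unmatched genome-wide
# variant sets (10 iterations) for the top genome-wide iQTLs.

library(iqtlkit)

seed <- 20260921L
gwas <- read.delim("results/gwas.tsv")
annotation <- read_annotation_tsv("results/data/annotation.tsv")

per_phen <- list()
rows <- list()
for (pid in unique(gwas$phenotype_id)) {
  sub <- gwas[gwas$phenotype_id == pid & gwas$suggested, ]
  if (!nrow(sub)) next
  tis <- sub("^([^:]+):.*$", "\\1", pid)
  res <- tryCatch(
    eqtl_enrichment(sub$variant_id, annotation, tis, n_perm = 100,
                    seed = stage_seed(seed, paste("enr", pid))),
    error = function(e) NULL)
  if (is.null(res)) next
  per_phen[[pid]] <- res
  rows[[length(rows) + 1]] <- data.frame(
    phenotype_id = pid, x = res$x, N = res$N, q = res$q,
    expected = res$expected, fold = res$fold, p = res$p)
}
tab <- do.call(rbind, rows)
if (!is.null(tab)) {
  tab$fdr <- bh_fdr(tab$p)
  pooled <- aggregate_enrichment(per_phen)
  write.table(tab, "results/eqtl_enrichment.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sum(tab$fdr < 0.1), "of", nrow(tab), "phenotypes with suggested",
      "iQTLs show same-tissue eQTL enrichment at FDR < 0.1.\n")
  cat(sprintf("Pooled: %d observed vs %.1f expected eQTLs in %d iQTLs (P = %.3g).\n",
              pooled$x, pooled$expected, pooled$N, pooled$p))
}

top_hits <- local({
  gw <- gwas[gwas$genome_wide, ]
  unlist(lapply(split(gw, gw$phenotype_id), function(s)
    s$variant_id[which.min(s$combined_p)]), use.names = FALSE)
})
if (length(top_hits)) {
  res <- catalog_enrichment(unique(top_hits), annotation, n_iter = 10,
                            seed = stage_seed(seed, "catalog"))
  write.table(data.frame(x = res$x, N = res$N, q = res$q,
                         expected = res$expected, fold = res$fold,
                         p = res$p),
              "results/catalog_enrichment.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("Catalog test on %d top iQTLs: observed %.1f%% vs %.1f%% expected (fold %.1f, P = %.2g).\n",
              res$N, 100 * res$x / res$N, 100 * res$q, res$fold, res$p))
}
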