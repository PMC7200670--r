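#' Matched candidate pool for one variant
#'
#' Finds variants with minor allele frequency within `maf_tol` of the
#' target and an LD partner count within a tolerance taken from
#' `ld_tol_schedule`, trying the schedule in order and stopping at the
#' first non-empty pool (the default schedule requires an identical LD
#' count first, then relaxes to plus or minus one). The target itself is
#' always excluded. An empty pool after the full schedule is an explicit
#' error naming the target.
#'
#' @param target Variant id present in the annotation.
#' @param annotation data.frame with `variant_id`, `maf`,
#'   `ld_partner_count`.
#' @param maf_tol MAF matching tolerance.
#' @param ld_tol_schedule Increasing LD-count tolerances tried in order.
#' @return Character vector of matched variant ids.
#' @export
match_pool <- function(target, annotation, maf_tol = 0.01,
                       ld_tol_schedule = c(0, 1)) {
  i <- match(target, annotation$variant_id)
  if (is.na(i)) stop("target variant not in annotation: ", target)
  dm <- abs(annotation$maf - annotation$maf[i])
  dl <- abs(annotation$ld_partner_count - annotation$ld_partner_count[i])
  for (tol in ld_tol_schedule) {
    # small slack keeps the printed tolerance inclusive under binary
    # floating point (|0.30 - 0.29| must count as within 0.01)
    hit <- which(dm <= maf_tol + 1e-12 & dl <= tol)
    hit <- setdiff(hit, i)
    if (length(hit)) return(annotation$variant_id[hit])
  }
  stop("no matched variants for target ", target,
       " after the full LD tolerance schedule")
}

#' Null eQTL proportion from matched permutations
#'
#' For each permutation, draws one matched variant per iQTL (uniformly
#' from its pool, independently across iQTLs and permutations) and
#' records the proportion of the drawn set flagged as a same-tissue eQTL;
#' `q` is the mean proportion over permutations.
#'
#' @param iqtls Character vector of iQTL variant ids.
#' @param annotation Annotation table with `eqtl_<tissue>` flag columns.
#' @param tissue Tissue whose eQTL flags define success.
#' @param n_perm Number of permutations.
#' @param maf_tol,ld_tol_schedule Matching parameters for [match_pool()].
#' @param seed Integer seed.
#' @return List: `q` (mean null proportion) and `proportions`
#'   (per-permutation values).
#' @export
permutation_null_q <- function(iqtls, annotation, tissue, n_perm = 100,
                               maf_tol = 0.01, ld_tol_schedule = c(0, 1),
                               seed = 1L) {
  flag_col <- paste0("eqtl_", tissue)
  if (!flag_col %in% names(annotation)) stop("no eQTL flags for tissue ", tissue)
  pools <- lapply(iqtls, match_pool, annotation = annotation,
                  maf_tol = maf_tol, ld_tol_schedule = ld_tol_schedule)
  flags <- stats::setNames(annotation[[flag_col]], annotation$variant_id)
  set.seed(seed)
  props <- vapply(seq_len(n_perm), function(b) {
    draw <- vapply(pools, function(pool)
      pool[sample.int(length(pool), 1)], character(1))
    mean(flags[draw])
  }, numeric(1))
  list(q = mean(props), proportions = props)
}

#' Exact binomial enrichment test
#'
#' Exact binomial tail by direct summation of the probability mass
#' function (no normal approximation). One-sided `"greater"` gives
#' `P(X >= x | N, q)`; the two-sided alternative uses the
#' minimum-likelihood rule (summing all outcomes no more probable than
#' the observed one).
#'
#' @param x Observed success count (0 <= x <= N).
#' @param N Number of trials.
#' @param q Hypothesized success probability.
#' @param alternative `"greater"` or `"two.sided"`.
#' @return P-value.
#' @export
binomial_enrichment_test <- function(x, N, q,
                                     alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (x < 0 || x > N) stop("x must lie in [0, N]")
  if (q < 0 || q > 1) stop("q must lie in [0, 1]")
  d <- stats::dbinom(0:N, N, q)
  if (alternative == "greater") {
    sum(d[(x + 1):(N + 1)])
  } else {
    # minimum-likelihood two-sided rule with a relative slack for ties
    min(1, sum(d[d <= d[x + 1] * (1 + 1e-7)]))
  }
}

#' Build an enrichment result record
#'
#' @param x Observed overlap count.
#' @param N Number of iQTLs tested.
#' @param q Null overlap proportion.
#' @param alternative Test sidedness.
#' @return List of class `"iqtl_enrichment"`: `x`, `N`, `q`, `expected`,
#'   `fold`, `p`, `alternative`.
#' @export
enrichment_result <- function(x, N, q, alternative = "greater") {
  expected <- q * N
  list2 <- list(x = x, N = N, q = q, expected = expected,
                fold = if (expected > 0) x / expected else Inf,
                p = binomial_enrichment_test(x, N, q, alternative),
                alternative = alternative)
  structure(list2, class = "iqtl_enrichment")
}

#' Per-phenotype eQTL enrichment of iQTLs
#'
#' Combines the matched-permutation null with the exact binomial test:
#' the observed overlap is the number of iQTLs flagged as same-tissue
#' eQTLs, and the null proportion comes from [permutation_null_q()].
#'
#' @inheritParams permutation_null_q
#' @param alternative Test sidedness.
#' @return An `"iqtl_enrichment"` result.
#' @export
eqtl_enrichment <- function(iqtls, annotation, tissue, n_perm = 100,
                            maf_tol = 0.01, ld_tol_schedule = c(0, 1),
                            alternative = "greater", seed = 1L) {
  flag_col <- paste0("eqtl_", tissue)
  flags <- stats::setNames(annotation[[flag_col]], annotation$variant_id)
  x <- sum(flags[iqtls])
  null <- permutation_null_q(iqtls, annotation, tissue, n_perm = n_perm,
                             maf_tol = maf_tol,
                             ld_tol_schedule = ld_tol_schedule, seed = seed)
  enrichment_result(x, length(iqtls), null$q, alternative)
}

#' Aggregate enrichment results across phenotypes
#'
#' Pools per-phenotype results with an N-weighted null proportion:
#' `q_new = sum(N_p * q_p) / sum(N_p)`, pooled counts `x = sum(x_p)`,
#' `N = sum(N_p)`, expected `q_new * N`, and a pooled exact binomial test.
#'
#' @param results List of `"iqtl_enrichment"` objects.
#' @param alternative Sidedness of the pooled test.
#' @return An `"iqtl_enrichment"` result for the pooled counts.
#' @export
aggregate_enrichment <- function(results, alternative = "greater") {
  if (!length(results)) stop("empty input")
  Ns <- vapply(results, `[[`, numeric(1), "N")
  qs <- vapply(results, `[[`, numeric(1), "q")
  xs <- vapply(results, `[[`, numeric(1), "x")
  q_new <- sum(Ns * qs) / sum(Ns)
  enrichment_result(sum(xs), sum(Ns), q_new, alternative)
}

#' GWAS-catalog enrichment of iQTLs
#'
#' Tests whether the iQTL set carries more prior GWAS-catalog
#' associations than expected. Unlike the eQTL test, the null draws are
#' unmatched: each iteration samples `length(iqtls)` variants uniformly
#' without replacement from the whole annotation, and `q` is the mean
#' flagged proportion over iterations. The fold change is the observed
#' proportion over `q` and the P-value a one-sided exact binomial test.
#'
#' @param iqtls iQTL variant ids.
#' @param annotation Annotation table with a `catalog_flag` column.
#' @param n_iter Number of sampling iterations.
#' @param seed Integer seed.
#' @return An `"iqtl_enrichment"` result (with `fold`).
#' @export
catalog_enrichment <- function(iqtls, annotation, n_iter = 10, seed = 1L) {
  n <- length(iqtls)
  if (nrow(annotation) <= n) stop("annotation pool smaller than the iQTL set")
  flags <- stats::setNames(annotation$catalog_flag, annotation$variant_id)
  set.seed(seed)
  props <- vapply(seq_len(n_iter), function(b)
    mean(flags[sample(annotation$variant_id, n)]), numeric(1))
  q <- mean(props)
  enrichment_result(sum(flags[iqtls]), n, q, "greater")
}

#' Pearson correlation of gene expression with a phenotype
#'
#' Two-sided Pearson correlation test between a gene's expression vector
#' and an infiltration phenotype score vector.
#'
#' @param gene_expr Expression vector.
#' @param phenotype Aligned phenotype score vector.
#' @return List: `r`, `p`, `n`.
#' @export
expr_phenotype_correlation <- function(gene_expr, phenotype) {
  if (length(gene_expr) != length(phenotype)) stop("unaligned vectors")
  if (length(gene_expr) < 3) stop("need at least 3 samples")
  if (stats::sd(gene_expr) == 0 || stats::sd(phenotype) == 0)
    stop("constant input")
  ct <- stats::cor.test(gene_expr, phenotype, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(gene_expr))
}
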