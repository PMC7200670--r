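# Shared small fixtures, built once per test run.

fixture_signature <- function(seed = 5L) {
  make_signature(unique(default_subtype_map()$raw), c("colon", "skin"),
                 n_genes = 600, n_markers = 20, seed = seed)
}

fixture_cohort <- function(n = 60, tissues = c("colon", "skin"), seed = 3L) {
  generate_cohort(n, tissues, seed = seed)
}

null_effect_spec <- function(base = 0.04) {
  data.frame(cell_type = unique(default_subtype_map()$raw), base = base,
             beta_age = 0, beta_sex = 0, beta_snp = 0,
             snp_id = NA_character_, stringsAsFactors = FALSE)
}

# jittered pure T-cell reference profiles for spike-in panels
fixture_tcell_profiles <- function(sig, cell_type, n_refs = 5, seed = 9L) {
  set.seed(seed)
  p <- sapply(seq_len(n_refs), function(i)
    sig$profiles[, cell_type] * stats::rlnorm(nrow(sig$profiles), 0, 0.2))
  rownames(p) <- rownames(sig$profiles)
  p
}

# Build an iqtl_phenotype directly (for filter tests)
make_phenotype <- function(tissue, cell_type, rel, abs_, enr, presence_p) {
  ids <- paste0("s", seq_along(rel))
  structure(list(tissue = tissue, cell_type = cell_type, sample_ids = ids,
                 n = length(ids),
                 scores = list(relative = stats::setNames(rel, ids),
                               absolute = stats::setNames(abs_, ids),
                               enrichment = stats::setNames(enr, ids)),
                 presence_p = stats::setNames(presence_p, ids)),
            class = "iqtl_phenotype")
}

make_score_set <- function(mat, tissue, method = "relative",
                           presence_p = NULL) {
  structure(list(method = method, scores = mat,
                 tissue = stats::setNames(rep_len(tissue, nrow(mat)),
                                          rownames(mat)),
                 scaling_factor = NULL, presence_p = presence_p),
            class = "iqtl_scores")
}

# Independent two-sided Fisher oracle: full hypergeometric enumeration.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  xs <- lo:hi
  probs <- stats::dhyper(xs, r1, n - r1, c1)
  sum(probs[probs <= probs[xs == a] * (1 + 1e-7)])
}

# Closed-form HWE chi-square via the determinant identity (monomorphic
# variants carry no test: P = 1).
hwe_oracle <- function(n0, n1, n2) {
  if (2 * n0 + n1 == 0 || 2 * n2 + n1 == 0) return(1)
  n <- n0 + n1 + n2
  num <- n * (4 * n0 * n2 - n1^2)^2
  den <- (2 * n0 + n1)^2 * (2 * n2 + n1)^2
  stats::pchisq(num / den, df = 1, lower.tail = FALSE)
}
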