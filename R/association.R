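#' Hardy-Weinberg equilibrium chi-square P-value
#'
#' One-degree-of-freedom chi-square test without continuity correction on
#' the non-missing genotype counts, with expected counts from the observed
#' allele frequency.
#'
#' @param n0,n1,n2 Counts of the 0/1/2 dosage classes.
#' @return P-value (1 when the variant is monomorphic or n = 0).
#' @export
hwe_pvalue <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n == 0) return(1)
  p <- (2 * n0 + n1) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi <- sum((c(n0, n1, n2) - expd)^2 / expd)
  stats::pchisq(chi, df = 1, lower.tail = FALSE)
}

#' Genotype quality control
#'
#' Removes variants with minor allele frequency below 0.05, missingness
#' above 0.1, or Hardy-Weinberg P below 1e-6 (thresholds strict as
#' printed: MAF exactly 0.05 and missingness exactly 0.1 are kept).
#' Metadata are recomputed from the dosage matrix before filtering so the
#' decisions always reflect the data actually carried forward.
#'
#' @param genotypes An `iqtl_genotypes` object.
#' @param maf_min,miss_max,hwe_min QC thresholds.
#' @return List: `genotypes` (filtered `iqtl_genotypes`) and `removed`
#'   (data.frame `variant_id`, `reason` -- the first failing filter).
#' @export
qc_genotypes <- function(genotypes, maf_min = 0.05, miss_max = 0.1,
                         hwe_min = 1e-6) {
  meta <- variant_metadata(genotypes$dosage)
  bad_maf <- meta$maf < maf_min
  bad_miss <- meta$missing_rate > miss_max
  bad_hwe <- meta$hwe_p < hwe_min
  drop <- bad_maf | bad_miss | bad_hwe
  reason <- ifelse(bad_maf, "maf",
                   ifelse(bad_miss, "missingness", "hwe"))
  removed <- data.frame(variant_id = meta$variant_id[drop],
                        reason = reason[drop], stringsAsFactors = FALSE)
  out <- genotypes
  out$dosage <- genotypes$dosage[, !drop, drop = FALSE]
  out$variants <- genotypes$variants[!drop, , drop = FALSE]
  list(genotypes = out, removed = removed)
}

#' Genotype principal components
#'
#' Singular value decomposition of the centered, variance-standardized
#' dosage matrix with mean-imputed missing entries, for use as population
#' stratification covariates.
#'
#' @param dosage Donors x variants matrix (0/1/2/NA).
#' @param n_pcs Number of components returned.
#' @return Donors x `n_pcs` matrix of component scores.
#' @export
genotype_pcs <- function(dosage, n_pcs = 3) {
  imp <- dosage
  if (anyNA(imp)) {
    cm <- colMeans(imp, na.rm = TRUE)
    idx <- which(is.na(imp), arr.ind = TRUE)
    imp[idx] <- cm[idx[, 2]]
  }
  sds <- apply(imp, 2, stats::sd)
  imp <- scale(imp[, sds > 0, drop = FALSE])
  sv <- svd(imp, nu = n_pcs, nv = 0)
  pcs <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  dimnames(pcs) <- list(rownames(dosage), paste0("gPC", seq_len(n_pcs)))
  pcs
}

#' Covariate design matrix
#'
#' Dummy-codes the standard covariate model (age bin as numeric, sex
#' binary, death classification and collection site categorical with
#' baselines fixed by sorted label order, autolysis numeric, optional
#' genotype PCs). Factors with a single observed level are dropped; a
#' rank-deficient design is an error.
#'
#' @param covariates data.frame with `age_bin`, `sex`, `death_class`,
#'   `autolysis`, `site` (one row per sample/donor).
#' @param pcs Optional matrix of genotype PCs (same row order).
#' @return Numeric design matrix including an intercept.
#' @export
covariate_design <- function(covariates, pcs = NULL) {
  df <- data.frame(
    age_bin = covariates$age_bin,
    sex = factor(covariates$sex, levels = sort(unique(covariates$sex))),
    death_class = factor(covariates$death_class,
                         levels = sort(unique(covariates$death_class))),
    autolysis = covariates$autolysis,
    site = factor(covariates$site, levels = sort(unique(covariates$site)))
  )
  keep <- vapply(df, function(col) !is.factor(col) || nlevels(col) > 1,
                 logical(1))
  form <- stats::as.formula(paste("~", paste(names(df)[keep], collapse = " + ")))
  X <- stats::model.matrix(form, df)
  if (!is.null(pcs)) X <- cbind(X, pcs)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient covariate design")
  rownames(X) <- rownames(covariates)
  X
}

#' Residualize a phenotype and rank-normalize
#'
#' Ordinary least-squares residuals of the score vector against the
#' covariate design, followed by the rank-based inverse normal
#' transformation; the result is an approximately standard-normal vector
#' suitable for genome-wide scanning.
#'
#' @param y Phenotype score vector.
#' @param design Covariate design matrix from [covariate_design()].
#' @return Transformed residual vector.
#' @export
adjust_and_transform <- function(y, design) {
  if (length(y) <= ncol(design)) stop("more model parameters than samples")
  res <- stats::lm.fit(design, y)$residuals
  out <- rank_inverse_normal(res)
  names(out) <- names(y)
  out
}

#' Per-SNP simple linear regression scan
#'
#' Regresses the transformed phenotype on each variant's dosage with
#' pairwise deletion of missing genotypes, returning the slope, standard
#' error and two-sided t-test P-value. Variants with fewer than `min_n`
#' non-missing genotypes or zero dosage variance yield NA rows (a single
#' zero-variance variant is an error). The whole scan is a handful of
#' matrix products, so millions of variants stream through in seconds.
#'
#' @param z Named transformed phenotype vector (names = donor ids).
#' @param genotypes An `iqtl_genotypes` or a donors x variants dosage
#'   matrix with donor rownames.
#' @param min_n Minimum per-variant non-missing sample count.
#' @return data.frame: `variant_id`, `n`, `slope`, `se`, `p`.
#' @export
snp_scan <- function(z, genotypes, min_n = 10) {
  G <- if (inherits(genotypes, "iqtl_genotypes")) genotypes$dosage else genotypes
  common <- intersect(names(z), rownames(G))
  if (!length(common)) stop("no donors shared between phenotype and genotypes")
  z <- z[common]
  G <- G[common, , drop = FALSE]

  M <- !is.na(G)
  G0 <- G; G0[!M] <- 0
  n <- colSums(M)
  Sx <- colSums(G0)
  Sxx <- colSums(G0^2)
  Sy <- drop(crossprod(M, z))
  Syy <- drop(crossprod(M, z^2))
  Sxy <- drop(crossprod(G0, z))

  Sxx_c <- Sxx - Sx^2 / n
  Sxy_c <- Sxy - Sx * Sy / n
  Syy_c <- Syy - Sy^2 / n
  ok <- n >= min_n & Sxx_c > 1e-12
  if (ncol(G) == 1 && !ok) stop("zero dosage variance or too few genotypes")

  slope <- se <- p <- rep(NA_real_, ncol(G))
  slope[ok] <- Sxy_c[ok] / Sxx_c[ok]
  rss <- Syy_c[ok] - slope[ok]^2 * Sxx_c[ok]
  rss <- pmax(rss, 0)
  se[ok] <- sqrt(rss / (n[ok] - 2) / Sxx_c[ok])
  tt <- slope[ok] / se[ok]
  p[ok] <- 2 * stats::pt(-abs(tt), df = n[ok] - 2)
  data.frame(variant_id = colnames(G), n = n, slope = slope, se = se, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Age and sex effects from the full multiple regression
#'
#' Fits the phenotype against the complete covariate model (no prior
#' residualization) and reports the age and sex coefficient t-tests.
#'
#' @param y Phenotype score vector.
#' @param covariates Covariate data.frame as in [covariate_design()].
#' @param pcs Optional genotype PCs.
#' @return data.frame with rows `age` and `sex`: `term`, `slope`, `se`,
#'   `p`, `n`.
#' @export
age_sex_scan <- function(y, covariates, pcs = NULL) {
  X <- covariate_design(covariates, pcs)
  fit <- stats::lm(y ~ X - 1)
  cf <- summary(fit)$coefficients
  rn <- rownames(cf)
  age_row <- grep("age_bin$", rn)
  sex_row <- grep("sex", rn)
  if (!length(age_row) || !length(sex_row))
    stop("age or sex term missing from the fitted model")
  out <- data.frame(
    term = c("age", "sex"),
    slope = cf[c(age_row[1], sex_row[1]), 1],
    se = cf[c(age_row[1], sex_row[1]), 2],
    p = cf[c(age_row[1], sex_row[1]), 4],
    n = length(y), row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Brown combination from a precomputed covariance term
#'
#' Low-level kernel of Empirical Brown's method: with k P-values and the
#' summed pairwise covariance of the transformed score vectors, the Fisher
#' statistic `X = -2 sum(log p)` is referred to a rescaled chi-square with
#' `f = 2 E^2 / Var` degrees of freedom and scale `c = Var / (2 E)`, where
#' `E = 2k` and `Var = 4k + 2 * cov_sum`. With `cov_sum = 0` this is
#' exactly Fisher's method.
#'
#' @param p Vector of k P-values in (0, 1].
#' @param cov_sum Sum over pairs i < j of `cov(w_i, w_j)`.
#' @return Combined P-value in (0, 1].
#' @export
brown_combine <- function(p, cov_sum) {
  k <- length(p)
  if (k < 2) stop("need at least two P-values")
  if (any(p <= 0 | p > 1)) stop("P-values must lie in (0, 1]")
  E <- 2 * k
  Var <- 4 * k + 2 * cov_sum
  if (Var <= 0) {
    warning("non-positive estimated variance; falling back to independence")
    Var <- 4 * k
  }
  f <- 2 * E^2 / Var
  c_scale <- Var / (2 * E)
  X <- -2 * sum(log(p))
  out <- stats::pchisq(X / c_scale, df = f, lower.tail = FALSE)
  min(max(out, .Machine$double.xmin), 1)
}

#' Combine dependent P-values with Empirical Brown's method
#'
#' Each method's score vector is standardized and transformed through its
#' own right-continuous empirical CDF, `w_i(s) = -2 * log(ecdf_i(x_i(s)))`
#' (the ECDF is bounded below by 1/N, so no logs of zero occur). The
#' empirical covariance of the `w` vectors then rescales the chi-square
#' reference of Fisher's statistic via [brown_combine()]. Because only
#' ranks enter the ECDF, the result is invariant to increasing affine
#' rescaling of any score vector.
#'
#' @param p k method P-values in (0, 1] for the same term.
#' @param scores k x N matrix: the method score vectors the P-values were
#'   derived from (one row per method).
#' @return Combined P-value in (0, 1].
#' @export
ebm_combine <- function(p, scores) {
  k <- length(p)
  if (k < 2) stop("need at least two P-values")
  if (!is.matrix(scores) || nrow(scores) != k)
    stop("scores must be a k x N matrix aligned with p")
  if (any(p <= 0 | p > 1)) stop("P-values must lie in (0, 1]")
  brown_combine(p, ebm_covsum(scores))
}

#' Summed pairwise covariance of the Brown-transformed score vectors
#'
#' Standardizes each row of `scores`, pushes it through its own
#' right-continuous empirical CDF (floored at 1/N), applies
#' `w = -2 * log(ecdf)`, and returns the sum over pairs i < j of
#' `cov(w_i, w_j)`. Scanning many terms that share the same score vectors
#' (every SNP of a phenotype) only needs this once.
#'
#' @param scores k x N matrix of method score vectors.
#' @return Scalar covariance sum for [brown_combine()].
#' @export
ebm_covsum <- function(scores) {
  k <- nrow(scores)
  N <- ncol(scores)
  W <- matrix(0, k, N)
  for (i in seq_len(k)) {
    x <- scores[i, ]
    if (stats::sd(x) == 0) stop("degenerate (constant) score vector")
    x <- as.numeric(scale(x))
    ecdf_vals <- rank(x, ties.method = "max") / N  # right-continuous ECDF
    W[i, ] <- -2 * log(pmax(ecdf_vals, 1 / N))
  }
  cv <- stats::cov(t(W))
  sum(cv[upper.tri(cv)])
}

#' Benjamini-Hochberg adjusted P-values
#'
#' Standard step-up false discovery rate adjustment with enforced
#' monotonicity, order-preserving on the input index.
#'
#' @param p P-values in [0, 1].
#' @return Adjusted P-values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("P-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Flag association records by significance tier
#'
#' Adds strict-inequality flags for genome-wide significance, suggested
#' significance, and FDR significance.
#'
#' @param records data.frame with a `combined_p` column and optionally an
#'   `fdr` column.
#' @param genome_wide,suggested,fdr_level Tier thresholds.
#' @return The records with logical columns `genome_wide`, `suggested`,
#'   `fdr_significant` (the last only when `fdr` is present).
#' @export
significance_calls <- function(records, genome_wide = 5e-8,
                               suggested = 1e-5, fdr_level = 0.1) {
  records$genome_wide <- records$combined_p < genome_wide
  records$suggested <- records$combined_p < suggested
  if (!is.null(records$fdr)) records$fdr_significant <- records$fdr < fdr_level
  records
}
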