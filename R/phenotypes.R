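#' Merge raw subtype scores into analysis cell types
#'
#' Sums the raw subtype columns feeding each merged cell type, per the
#' supplied mapping. Specific cell types are expected to draw on disjoint
#' subtype sets so that totals are conserved; composite types (e.g.
#' lymphoid, myeloid, or a CD4 composite) may overlap the specific ones,
#' and no renormalization is applied after merging.
#'
#' @param scores An `iqtl_scores` object or samples x subtypes matrix.
#' @param map data.frame with columns `raw` and `merged`.
#' @return Same shape as the input with merged cell-type columns.
#' @export
merge_subtypes <- function(scores, map) {
  mat <- if (inherits(scores, "iqtl_scores")) scores$scores else scores
  unknown <- setdiff(map$raw, colnames(mat))
  if (length(unknown)) stop("unknown raw label in map: ",
                            paste(unknown, collapse = ", "))
  merged_labels <- unique(map$merged)
  out <- sapply(merged_labels, function(m) {
    cols <- map$raw[map$merged == m]
    rowSums(mat[, cols, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(mat),
                dimnames = list(rownames(mat), merged_labels))
  if (inherits(scores, "iqtl_scores")) {
    scores$scores <- out
    scores
  } else out
}

#' Enumerate tissue-by-cell-type infiltration phenotypes
#'
#' Builds one candidate phenotype per (tissue, cell type) pair from three
#' aligned score sets, intersecting the sample ids available in all three
#' methods within the tissue. The number of phenotypes is always the
#' number of shared cell types times the number of tissues, including
#' pairs left with zero matched samples.
#'
#' @param relative,absolute,enrichment `iqtl_scores` objects (methods as
#'   named) sharing cell-type columns and carrying per-sample tissues.
#' @return List of `"iqtl_phenotype"` objects, each with `tissue`,
#'   `cell_type`, `sample_ids`, `n`, `scores` (named list of the three
#'   aligned vectors) and `presence_p` (from the relative scorer, if
#'   available).
#' @export
build_phenotypes <- function(relative, absolute, enrichment) {
  sets <- list(relative = relative, absolute = absolute,
               enrichment = enrichment)
  stopifnot(all(vapply(sets, inherits, logical(1), "iqtl_scores")))
  cts <- Reduce(intersect, lapply(sets, function(s) colnames(s$scores)))
  tissues <- sort(unique(unlist(lapply(sets, function(s) unique(s$tissue)))))
  if (!length(cts)) stop("no shared cell types across methods")

  phens <- list()
  for (tis in tissues) {
    ids <- Reduce(intersect, lapply(sets, function(s)
      rownames(s$scores)[s$tissue == tis]))
    for (ct in cts) {
      ph <- structure(list(
        tissue = tis, cell_type = ct, sample_ids = ids, n = length(ids),
        scores = lapply(sets, function(s) s$scores[ids, ct]),
        presence_p = if (!is.null(relative$presence_p))
          relative$presence_p[ids] else NULL
      ), class = "iqtl_phenotype")
      phens[[paste(tis, ct, sep = ":")]] <- ph
    }
  }
  phens
}

#' Default phenotype filter thresholds
#'
#' The filter keeps a phenotype only when the tissue has more than
#' `n_min` matched samples, more than `presence_frac` of its samples show
#' detectable immune content (relative-method presence P below
#' `presence_p_max`), the cell type is a substantial part of the immune
#' content (mean relative score above `mean_rel_min` and mean enrichment
#' score above `mean_enr_min`), absolute and enrichment scores do not
#' negatively correlate, and the tissue is not an excluded (cell-line)
#' tissue. All boundaries are strict as printed: n equal to `n_min` fails,
#' a correlation of exactly 0 passes.
#'
#' @param n_min Minimum sample size (exclusive).
#' @param presence_frac Required fraction of present samples (exclusive).
#' @param presence_p_max Presence P cutoff defining a present sample.
#' @param mean_rel_min Mean relative-score threshold (exclusive).
#' @param mean_enr_min Mean enrichment-score threshold (exclusive).
#' @param corr_min Minimum allowed absolute/enrichment correlation
#'   (inclusive).
#' @param excluded_tissues Tissues removed outright.
#' @param epsilon Offset used by [ratio_phenotype()].
#' @return List of thresholds.
#' @export
filter_criteria <- function(n_min = 70, presence_frac = 0.5,
                            presence_p_max = 0.50, mean_rel_min = 0.05,
                            mean_enr_min = 0.001, corr_min = 0,
                            excluded_tissues = character(0),
                            epsilon = 1e-10) {
  list(n_min = n_min, presence_frac = presence_frac,
       presence_p_max = presence_p_max, mean_rel_min = mean_rel_min,
       mean_enr_min = mean_enr_min, corr_min = corr_min,
       excluded_tissues = excluded_tissues, epsilon = epsilon)
}

#' Apply the five-criterion phenotype filter
#'
#' A phenotype is kept iff every criterion passes; the audit table records
#' each criterion's value, threshold and outcome, and the first failing
#' criterion per phenotype. Filtering is order-independent and idempotent.
#'
#' @param phenotypes List of `iqtl_phenotype` objects.
#' @param criteria Thresholds from [filter_criteria()].
#' @return List with `kept` (the surviving phenotypes) and `audit`
#'   (data.frame: `phenotype_id`, `criterion`, `value`, `threshold`,
#'   `pass`, `kept`, `first_fail`).
#' @export
filter_phenotypes <- function(phenotypes, criteria = filter_criteria()) {
  rows <- list()
  kept <- logical(length(phenotypes))
  for (i in seq_along(phenotypes)) {
    ph <- phenotypes[[i]]
    id <- paste(ph$tissue, ph$cell_type, sep = ":")
    pres <- if (!is.null(ph$presence_p) && ph$n > 0)
      mean(ph$presence_p < criteria$presence_p_max) else 0
    co <- if (ph$n >= 3 && stats::sd(ph$scores$absolute) > 0 &&
              stats::sd(ph$scores$enrichment) > 0)
      stats::cor(ph$scores$absolute, ph$scores$enrichment) else NA_real_
    checks <- data.frame(
      criterion = c("sample_size", "presence", "mean_relative",
                    "mean_enrichment", "correlation", "cell_line"),
      value = c(ph$n, pres,
                if (ph$n) mean(ph$scores$relative) else 0,
                if (ph$n) mean(ph$scores$enrichment) else 0,
                co,
                as.numeric(ph$tissue %in% criteria$excluded_tissues)),
      threshold = c(criteria$n_min, criteria$presence_frac,
                    criteria$mean_rel_min, criteria$mean_enr_min,
                    criteria$corr_min, 0),
      stringsAsFactors = FALSE
    )
    checks$pass <- c(
      ph$n > criteria$n_min,
      pres > criteria$presence_frac,
      checks$value[3] > criteria$mean_rel_min,
      checks$value[4] > criteria$mean_enr_min,
      !is.na(co) && co >= criteria$corr_min,
      !(ph$tissue %in% criteria$excluded_tissues)
    )
    kept[i] <- all(checks$pass)
    checks$phenotype_id <- id
    checks$kept <- kept[i]
    ff <- checks$criterion[!checks$pass]
    checks$first_fail <- if (length(ff)) ff[1] else NA_character_
    rows[[i]] <- checks
  }
  audit <- do.call(rbind, rows)
  audit <- audit[, c("phenotype_id", "criterion", "value", "threshold",
                     "pass", "kept", "first_fail")]
  rownames(audit) <- NULL
  list(kept = phenotypes[kept], audit = audit)
}

#' Rank-based inverse normal transformation
#'
#' Maps values to Gaussian quantiles `qnorm((rank - 0.5) / n)` with
#' average ranks for ties. A constant vector has no rank information and
#' is rejected rather than silently mapped to zeros.
#'
#' @param x Numeric vector without NAs.
#' @param offset Rank offset (default 0.5).
#' @return Transformed vector; for distinct inputs, a permutation of the
#'   fixed quantile set `qnorm((k - 0.5) / n)`.
#' @export
rank_inverse_normal <- function(x, offset = 0.5) {
  if (anyNA(x)) stop("NA values in input")
  if (length(unique(x)) < 2) stop("cannot transform a constant vector")
  stats::qnorm((rank(x, ties.method = "average") - offset) / length(x))
}

#' Ratio phenotype with epsilon offset and rank-normalization
#'
#' Computes `(numerator + epsilon) / (denominator + epsilon)` elementwise
#' (the offset keeps zero-over-zero ratios finite and equal to 1) and
#' applies the rank-based inverse normal transformation to tame extreme
#' outliers.
#'
#' @param numerator,denominator Aligned non-negative score vectors.
#' @param epsilon Offset added to both sides (default 1e-10).
#' @return Transformed ratio vector (all finite).
#' @export
ratio_phenotype <- function(numerator, denominator, epsilon = 1e-10) {
  if (length(numerator) != length(denominator)) stop("unaligned vectors")
  rank_inverse_normal((numerator + epsilon) / (denominator + epsilon))
}

#' Regress infiltration phenotypes on expression principal components
#'
#' Performs a principal component analysis of the expression matrix
#' (genes centered, and by default scaled to unit variance) and fits a
#' simple linear regression of each phenotype score vector on each of the
#' first `n_pcs` sample-space components, with Benjamini-Hochberg
#' adjustment across all (phenotype, PC) pairs.
#'
#' @param expression Genes x samples matrix, columns matched to the
#'   phenotype vectors.
#' @param phenotype_scores Samples x phenotypes matrix (or a single
#'   vector) of absolute scores.
#' @param n_pcs Number of leading components tested.
#' @param scale_genes Scale genes to unit variance before the PCA.
#' @param fdr_level Significance level on the adjusted P-values.
#' @return data.frame: `phenotype`, `pc`, `slope`, `p`, `fdr`,
#'   `significant`.
#' @export
pc_phenotype_scan <- function(expression, phenotype_scores, n_pcs = 4,
                              scale_genes = TRUE, fdr_level = 0.1) {
  if (is.vector(phenotype_scores))
    phenotype_scores <- matrix(phenotype_scores,
                               dimnames = list(names(phenotype_scores), "phenotype1"))
  n <- ncol(expression)
  if (n < n_pcs + 2) stop("need at least n_pcs + 2 samples")
  keep <- apply(expression, 1, stats::sd) > 0
  pca <- stats::prcomp(t(expression[keep, , drop = FALSE]), center = TRUE,
                       scale. = scale_genes)
  if (ncol(pca$x) < n_pcs) stop("expression matrix is rank deficient")
  pcs <- pca$x[, seq_len(n_pcs), drop = FALSE]

  res <- list()
  for (j in seq_len(ncol(phenotype_scores))) {
    for (k in seq_len(n_pcs)) {
      fit <- summary(stats::lm(phenotype_scores[, j] ~ pcs[, k]))$coefficients
      res[[length(res) + 1]] <- data.frame(
        phenotype = colnames(phenotype_scores)[j], pc = paste0("PC", k),
        slope = fit[2, 1], p = fit[2, 4], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$fdr < fdr_level
  out
}
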