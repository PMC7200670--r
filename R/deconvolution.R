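#' Non-negative least squares by active-set iteration
#'
#' Solves `min ||A x - b||` subject to `x >= 0` with the Lawson-Hanson
#' active-set method on the normal equations. The signature matrices used
#' for scoring have few columns, so each call reduces to a handful of tiny
#' linear solves; this is what makes the 1000-permutation presence test
#' affordable.
#'
#' @param A Numeric matrix (genes x cell types).
#' @param b Numeric vector of length `nrow(A)`.
#' @param tol Dual-feasibility tolerance; defaults to a multiple of machine
#'   epsilon scaled by the problem.
#' @return Non-negative coefficient vector of length `ncol(A)`.
#' @export
nnls_fit <- function(A, b, tol = NULL) {
  AtA <- crossprod(A)
  Atb <- drop(crossprod(A, b))
  k <- length(Atb)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(AtA)) * k
  x <- numeric(k)
  passive <- logical(k)
  w <- Atb
  it <- 0L
  while (any(!passive & w > tol) && it < 30L * k) {
    it <- it + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(k)
      P <- which(passive)
      s[P] <- solve(AtA[P, P, drop = FALSE], Atb[P])
      if (all(s[P] > tol)) break
      neg <- P[s[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    x <- s
    w <- Atb - drop(AtA %*% x)
  }
  pmax(x, 0)
}

#' Relative cell-type fractions for one sample
#'
#' Fits the sample profile restricted to the signature genes as a
#' non-negative combination of the signature columns and renormalizes the
#' weights to sum to one. The default constrained-least-squares mode is
#' deterministic; a nu-support-vector-regression mode (linear kernel,
#' negative coefficients clipped) is available behind the same contract
#' when the e1071 package is installed.
#'
#' @param profile Named expression vector covering the signature genes.
#' @param signature An `iqtl_signature`.
#' @param mode `"cls"` (default) or `"svr"`.
#' @param nu SVR nu parameter (svr mode only).
#' @return List: `fractions` (non-negative, summing to 1 when any signal is
#'   detected), `raw` (unnormalized weights), `residual` (relative fit
#'   residual on the signature genes).
#' @export
score_relative <- function(profile, signature, mode = c("cls", "svr"),
                           nu = 0.5) {
  mode <- match.arg(mode)
  S <- signature$matrix
  if (ncol(S) < 2) stop("need at least two cell types")
  miss <- setdiff(rownames(S), names(profile))
  if (length(miss)) stop("signature genes missing from profile: ",
                         paste(utils::head(miss, 3), collapse = ", "))
  x <- profile[rownames(S)]
  if (all(x == 0)) stop("profile is all zero on the signature genes")

  if (mode == "cls") {
    w <- nnls_fit(S, x)
  } else {
    if (!requireNamespace("e1071", quietly = TRUE))
      stop("mode 'svr' requires the e1071 package")
    fit <- e1071::svm(S, x, type = "nu-regression", kernel = "linear",
                      nu = nu, scale = FALSE)
    w <- pmax(drop(crossprod(fit$coefs, fit$SV)), 0)
    names(w) <- colnames(S)
  }
  names(w) <- colnames(S)
  fr <- if (sum(w) > 0) w / sum(w) else w
  resid <- sqrt(sum((x - drop(S %*% w))^2)) / sqrt(sum(x^2))
  list(fractions = fr, raw = w, residual = resid)
}

#' Per-sample scaling factor for total immune content
#'
#' Ratio of the median expression over the signature-matrix genes to the
#' median expression over all genes. The formula is a package design
#' choice; its contract is that the factor is monotone in the true total
#' immune fraction on spiked mixtures, which the test suite asserts.
#'
#' @param profile Named expression vector (all genes).
#' @param signature An `iqtl_signature`.
#' @return Positive scalar.
#' @export
scaling_factor <- function(profile, signature) {
  if (all(profile == 0)) stop("profile is all zero")
  sig_genes <- intersect(rownames(signature$matrix), names(profile))
  stats::median(profile[sig_genes]) / stats::median(profile)
}

#' Absolute scores from relative scores and scaling factors
#'
#' Elementwise product of each sample's relative fractions with its scaling
#' factor; zeros are preserved and the within-sample ratio between cell
#' types is unchanged.
#'
#' @param relative An `iqtl_scores` object with method `"relative"`.
#' @param factors Per-sample positive scalars, aligned with (or named by)
#'   the samples of `relative`.
#' @return An `iqtl_scores` object with method `"absolute"`.
#' @export
score_absolute <- function(relative, factors) {
  stopifnot(inherits(relative, "iqtl_scores"))
  ids <- rownames(relative$scores)
  if (!is.null(names(factors))) factors <- factors[ids]
  if (length(factors) != length(ids)) stop("factors not aligned with samples")
  if (any(factors < 0)) stop("negative scaling factor")
  out <- relative
  out$method <- "absolute"
  out$scores <- relative$scores * factors
  out$scaling_factor <- factors
  out
}

#' Rank-based single-sample enrichment scores
#'
#' For each sample, genes are ranked by decreasing expression and each gene
#' set is scored with a weighted running-sum statistic: hits accumulate
#' weight `(N - position + 1)^exponent`, misses accumulate uniformly, and
#' the score is the maximum deviation of the hit curve above the miss
#' curve, floored at 0. A set occupying the top ranks scores 1. Scores are
#' comparable across samples within a single-tissue batch only, so the
#' function refuses mixed-tissue batches.
#'
#' @param expression Genes x samples matrix (one tissue batch).
#' @param gene_sets Named list of gene-id vectors (all non-empty).
#' @param tissues Optional per-sample tissue labels used to enforce the
#'   single-tissue precondition.
#' @param exponent Rank weight exponent.
#' @return Samples x gene sets score matrix.
#' @export
score_enrichment <- function(expression, gene_sets, tissues = NULL,
                             exponent = 0.25) {
  if (!is.null(tissues) && length(unique(tissues)) > 1)
    stop("enrichment scoring requires a single-tissue batch")
  if (any(lengths(gene_sets) == 0)) stop("empty gene set")
  genes <- rownames(expression)
  n <- length(genes)
  sets <- lapply(gene_sets, function(g) {
    idx <- match(g, genes)
    if (anyNA(idx)) stop("gene set member absent from expression matrix")
    idx
  })
  w_rank <- (n - seq_len(n) + 1)^exponent
  out <- matrix(0, ncol(expression), length(sets),
                dimnames = list(colnames(expression), names(gene_sets)))
  for (s in seq_len(ncol(expression))) {
    ord <- order(expression[, s], decreasing = TRUE)
    pos <- integer(n)
    pos[ord] <- seq_len(n)
    for (k in seq_along(sets)) {
      hit <- logical(n)
      hit[pos[sets[[k]]]] <- TRUE
      hw <- ifelse(hit, w_rank, 0)
      p_hit <- cumsum(hw) / sum(hw)
      p_miss <- cumsum(!hit) / (n - length(sets[[k]]))
      out[s, k] <- max(0, max(p_hit - p_miss))
    }
  }
  out
}

#' Permutation presence P-value for immune content
#'
#' Tests the null hypothesis that no reference immune cells are present in
#' the sample. The statistic is the Pearson correlation between the
#' NNLS-reconstructed and the observed profile over the signature genes;
#' the null distribution is obtained by shuffling gene labels of the whole
#' profile and refitting. `P = (1 + #{permuted >= observed}) / (n_perm +
#' 1)`, so P is always in (0, 1].
#'
#' @param profile Named expression vector (all genes).
#' @param signature An `iqtl_signature`.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return Probability in (0, 1].
#' @export
presence_pvalue <- function(profile, signature, n_perm = 1000, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  set.seed(seed)
  S <- signature$matrix
  m <- nrow(S)
  obs_stat <- .presence_stat(S, profile[rownames(S)])
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    xp <- sample(profile, m)
    if (.presence_stat(S, xp) >= obs_stat) exceed <- exceed + 1L
  }
  (1 + exceed) / (n_perm + 1)
}

.presence_stat <- function(S, x) {
  w <- nnls_fit(S, x)
  recon <- drop(S %*% w)
  if (stats::sd(recon) == 0 || stats::sd(x) == 0) return(-1)
  stats::cor(recon, x)
}

#' Score a whole expression matrix with one method
#'
#' Convenience wrapper producing an `iqtl_scores` object (method,
#' samples x cell types score matrix, per-sample tissue, scaling factor and
#' presence P-value where the method defines them). Relative and absolute
#' scoring work sample-by-sample; enrichment scoring is batched per tissue.
#'
#' @param expression Genes x samples matrix.
#' @param signature An `iqtl_signature`.
#' @param tissues Per-sample tissue labels (defaults to one batch).
#' @param method `"relative"`, `"absolute"` or `"enrichment"`.
#' @param presence Logical: compute permutation presence P-values
#'   (relative/absolute only).
#' @param n_perm Permutations for the presence test.
#' @param seed Seed for the presence permutations.
#' @return An `iqtl_scores` object.
#' @export
deconvolve <- function(expression, signature, tissues = NULL,
                       method = c("relative", "absolute", "enrichment"),
                       presence = FALSE, n_perm = 1000, seed = 1L) {
  method <- match.arg(method)
  ns <- ncol(expression)
  if (is.null(tissues)) tissues <- rep("batch1", ns)
  tissues <- stats::setNames(rep_len(tissues, ns), colnames(expression))

  if (method == "enrichment") {
    parts <- lapply(split(seq_len(ns), tissues), function(idx)
      score_enrichment(expression[, idx, drop = FALSE], signature$gene_sets))
    sc <- do.call(rbind, parts)[colnames(expression), , drop = FALSE]
    return(structure(list(method = "enrichment", scores = sc,
                          tissue = tissues, scaling_factor = NULL,
                          presence_p = NULL), class = "iqtl_scores"))
  }

  k <- ncol(signature$matrix)
  sc <- matrix(0, ns, k, dimnames = list(colnames(expression),
                                         colnames(signature$matrix)))
  fac <- numeric(ns)
  for (s in seq_len(ns)) {
    sc[s, ] <- score_relative(expression[, s], signature)$fractions
    fac[s] <- scaling_factor(expression[, s], signature)
  }
  names(fac) <- colnames(expression)
  pp <- NULL
  if (presence) {
    pp <- vapply(seq_len(ns), function(s)
      presence_pvalue(expression[, s], signature, n_perm = n_perm,
                      seed = seed + s), numeric(1))
    names(pp) <- colnames(expression)
  }
  rel <- structure(list(method = "relative", scores = sc, tissue = tissues,
                        scaling_factor = fac, presence_p = pp),
                   class = "iqtl_scores")
  if (method == "relative") rel else score_absolute(rel, fac)
}

#' Correlate estimated scores with planted truth
#'
#' Computes the per-cell-type Pearson correlation between estimated scores
#' and the true fractions under one of the two truth definitions: the
#' `"tissue"` scenario (fraction of the whole sample) or the `"immune"`
#' scenario (fraction of the immune compartment).
#'
#' @param scores An `iqtl_scores` object or a samples x cell types matrix.
#' @param design An `iqtl_design` carrying the truth matrices.
#' @param scenario `"tissue"` or `"immune"`.
#' @return Named vector of Pearson r per cell type (NA, with a warning,
#'   where either side is constant).
#' @export
evaluate_scenarios <- function(scores, design, scenario = c("tissue", "immune")) {
  scenario <- match.arg(scenario)
  est <- if (inherits(scores, "iqtl_scores")) scores$scores else scores
  truth <- if (scenario == "tissue") design$tissue_frac else design$immune_frac
  if (nrow(est) < 3) stop("need at least 3 samples")
  ids <- intersect(rownames(est), rownames(truth))
  cts <- intersect(colnames(est), colnames(truth))
  if (!length(cts)) stop("no shared cell types between scores and truth")
  r <- vapply(cts, function(ct) {
    e <- est[ids, ct]; t <- truth[ids, ct]
    if (stats::sd(e) == 0 || stats::sd(t) == 0) {
      warning("constant estimates or truth for ", ct)
      return(NA_real_)
    }
    stats::cor(e, t)
  }, numeric(1))
  r
}
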