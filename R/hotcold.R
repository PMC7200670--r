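#' Consensus k-means clustering of a score vector
#'
#' Runs resampled k-means over a range of cluster numbers on a single
#' score vector. Following the described procedure, the 1 x N vector is
#' cloned into three identical rows before clustering (mathematically a
#' rescaling of Euclidean distances, reproduced literally so the distance
#' computations match). Each resampling cycle subsamples items without
#' replacement and accumulates, per pair, how often the two samples were
#' clustered together among the cycles in which both were drawn.
#'
#' @param scores Numeric score vector (names kept as sample ids).
#' @param k_range Candidate cluster numbers (each < N).
#' @param n_resample Resampling cycles per k.
#' @param subsample_frac Fraction of samples drawn per cycle.
#' @param nstart k-means restarts per cycle.
#' @param seed Integer seed.
#' @return List of class `"iqtl_consensus"`: per k, `M` (N x N consensus
#'   proportion matrix, unit diagonal) and `assignments` (k-means labels
#'   from a full-data run used for downstream labelling); plus `k_range`
#'   and `n`.
#' @export
consensus_kmeans <- function(scores, k_range = 2:20, n_resample = 2000,
                             subsample_frac = 0.8, nstart = 10, seed = 1L) {
  N <- length(scores)
  if (stats::sd(scores) == 0) stop("constant score vector")
  if (N <= max(k_range)) stop("need more samples than the largest k")
  set.seed(seed)
  X <- cbind(scores, scores, scores)  # the 3-row cloning, samples in rows
  ids <- if (!is.null(names(scores))) names(scores) else as.character(seq_len(N))
  m <- max(2L, ceiling(subsample_frac * N))

  per_k <- list()
  for (k in k_range) {
    I <- matrix(0, N, N)
    C <- matrix(0, N, N)
    for (b in seq_len(n_resample)) {
      idx <- sample.int(N, m)
      cl <- stats::kmeans(X[idx, , drop = FALSE], centers = k,
                          nstart = nstart)$cluster
      same <- outer(cl, cl, "==")
      I[idx, idx] <- I[idx, idx] + same
      C[idx, idx] <- C[idx, idx] + 1
    }
    M <- ifelse(C > 0, I / C, 0)
    diag(M) <- 1
    dimnames(M) <- list(ids, ids)
    full <- stats::kmeans(X, centers = k, nstart = nstart)$cluster
    names(full) <- ids
    per_k[[as.character(k)]] <- list(M = M, assignments = full)
  }
  structure(list(runs = per_k, k_range = k_range, n = N),
            class = "iqtl_consensus")
}

#' Empirical CDF of consensus matrix entries
#'
#' `CDF(c) = sum_{i<j} 1{M(i,j) <= c} / (N(N-1)/2)`: the fraction of
#' off-diagonal pairs whose co-clustering proportion does not exceed c.
#'
#' @param M N x N consensus matrix.
#' @param grid Threshold grid in [0, 1].
#' @return Vector of CDF values along the grid.
#' @export
consensus_cdf <- function(M, grid = seq(0, 1, by = 0.01)) {
  vals <- M[upper.tri(M)]
  vapply(grid, function(c) mean(vals <= c), numeric(1))
}

#' Choose the number of clusters by the delta-area rule
#'
#' Computes the area under the consensus CDF for each candidate k and the
#' relative change in area between consecutive k (the area itself for the
#' smallest k), returning the k with the maximum observed relative change;
#' ties break toward smaller k.
#'
#' @param consensus An `iqtl_consensus` object, or a named list of
#'   consensus matrices keyed by k.
#' @param grid Threshold grid for the CDF.
#' @return List: `k` (chosen), `table` (per k: `area`, `delta`).
#' @export
select_k <- function(consensus, grid = seq(0, 1, by = 0.01)) {
  mats <- if (inherits(consensus, "iqtl_consensus"))
    lapply(consensus$runs, `[[`, "M") else consensus
  ks <- as.integer(names(mats))
  if (length(ks) < 2) stop("need at least two candidate k values")
  ord <- order(ks)
  ks <- ks[ord]; mats <- mats[ord]
  area <- vapply(mats, function(M) {
    cdf <- consensus_cdf(M, grid)
    sum(diff(grid) * cdf[-1])
  }, numeric(1))
  delta <- c(area[1], diff(area) / area[-length(area)])
  chosen <- ks[which.max(delta)]
  list(k = chosen, table = data.frame(k = ks, area = area, delta = delta,
                                      row.names = NULL))
}

#' Label clusters as hot, cold or intermediate
#'
#' Computes the mean score per cluster; every sample in the maximum-mean
#' cluster is labelled hot, every sample in the minimum-mean cluster cold,
#' and the rest intermediate. Exact mean ties break deterministically
#' toward the smallest cluster index.
#'
#' @param assignments Integer cluster labels per sample.
#' @param scores Aligned score vector.
#' @return Character vector of labels (`"hot"`, `"cold"`,
#'   `"intermediate"`), named like `scores` when it has names.
#' @export
label_hot_cold <- function(assignments, scores) {
  cl <- sort(unique(assignments))
  if (length(cl) < 2) stop("need at least two clusters")
  means <- vapply(cl, function(c) mean(scores[assignments == c]), numeric(1))
  hot <- cl[which.max(means)]
  cold <- cl[which.min(means)]
  lab <- rep("intermediate", length(assignments))
  lab[assignments == hot] <- "hot"
  lab[assignments == cold] <- "cold"
  names(lab) <- names(scores)
  lab
}

#' Quintile-based hot and cold labels
#'
#' Hot samples sit at or above the (1 - q) nearest-rank quantile in all
#' three method score vectors; cold samples at or below the q quantile in
#' all three. Nearest-rank cutoffs make the label sets deterministic, and
#' a larger q yields a superset of hot labels.
#'
#' @param score_list List of three aligned score vectors (one per method).
#' @param q Quantile fraction (default 0.2; 0.4 for the relaxed variant).
#' @return Character label vector (`"hot"`, `"cold"`, `"intermediate"`).
#' @export
quintile_labels <- function(score_list, q = 0.2) {
  n <- length(score_list[[1]])
  stopifnot(all(lengths(score_list) == n))
  # nearest-rank cuts sized so that distinct scores give exactly
  # floor(q * n) samples on each side
  cut_hi <- function(x) sort(x)[min(n, n - floor(q * n) + 1L)]
  cut_lo <- function(x) sort(x)[max(1L, floor(q * n))]
  hot <- Reduce(`&`, lapply(score_list, function(x) x >= cut_hi(x)))
  cold <- Reduce(`&`, lapply(score_list, function(x) x <= cut_lo(x)))
  lab <- rep("intermediate", n)
  lab[cold] <- "cold"
  lab[hot] <- "hot"
  names(lab) <- names(score_list[[1]])
  lab
}

#' Intersect hot/cold labels across methods
#'
#' A sample is consensus hot only when every method labels it hot, and
#' consensus cold only when every method labels it cold; the order of
#' intersection is immaterial.
#'
#' @param label_list List of aligned label vectors (one per method).
#' @return List with character vectors `hot` and `cold` of sample ids (or
#'   indices when labels are unnamed).
#' @export
consensus_across_methods <- function(label_list) {
  ids_of <- function(lab, what) {
    nm <- names(lab)
    if (is.null(nm)) nm <- as.character(seq_along(lab))
    nm[lab == what]
  }
  list(hot = Reduce(intersect, lapply(label_list, ids_of, "hot")),
       cold = Reduce(intersect, lapply(label_list, ids_of, "cold")))
}

#' Per-donor hot-tissue burden
#'
#' Restricted to donors sampled in at least `min_tissues` tissues, counts
#' in how many of their tissues each donor is labelled hot, the
#' corresponding fraction, and the modal hot-tissue count across donors
#' (smallest count on ties).
#'
#' @param labels data.frame with columns `donor_id`, `tissue`, `label`.
#' @param min_tissues Minimum sampled tissues per donor.
#' @return List: `per_donor` (data.frame `donor_id`, `n_tissues`,
#'   `n_hot`, `fraction`) and `mode_hot` (modal hot count).
#' @export
hot_burden <- function(labels, min_tissues = 8) {
  n_tis <- tapply(labels$tissue, labels$donor_id,
                  function(t) length(unique(t)))
  eligible <- names(n_tis)[n_tis >= min_tissues]
  per <- lapply(eligible, function(d) {
    sub <- labels[labels$donor_id == d, ]
    data.frame(donor_id = d, n_tissues = length(unique(sub$tissue)),
               n_hot = sum(sub$label == "hot"), stringsAsFactors = FALSE)
  })
  per <- if (length(per)) do.call(rbind, per) else
    data.frame(donor_id = character(0), n_tissues = integer(0),
               n_hot = integer(0))
  per$fraction <- ifelse(per$n_tissues > 0, per$n_hot / per$n_tissues, NA)
  mode_hot <- if (nrow(per)) {
    tab <- table(per$n_hot)
    as.integer(names(tab)[which.max(tab)])
  } else NA_integer_
  list(per_donor = per, mode_hot = mode_hot)
}

#' Fisher test of hot-pattern independence between tissues
#'
#' For every pair of tissues, builds the two-by-two table of hot versus
#' not-hot status over the donors sampled in both tissues and applies the
#' Fisher exact test (two-sided by default) of independent hot-sharing.
#' The Bonferroni per-test threshold is 0.05 divided by the number of
#' pairs tested; degenerate tables (a zero margin) are logged with P = 1.
#'
#' @param labels data.frame with columns `donor_id`, `tissue`, `label`.
#' @param alpha Family-wise error level for the Bonferroni threshold.
#' @param alternative Sidedness passed to the Fisher test.
#' @return data.frame per pair: `tissue_a`, `tissue_b`, `n`, the four
#'   table counts, `p`, `degenerate`, `threshold`, `significant`.
#' @export
hot_sharing_test <- function(labels, alpha = 0.05,
                             alternative = "two.sided") {
  tissues <- sort(unique(labels$tissue))
  if (length(tissues) < 2) stop("need at least two tissues")
  pairs <- utils::combn(tissues, 2)
  res <- list()
  for (j in seq_len(ncol(pairs))) {
    ta <- pairs[1, j]; tb <- pairs[2, j]
    a <- labels[labels$tissue == ta, ]
    b <- labels[labels$tissue == tb, ]
    donors <- intersect(a$donor_id, b$donor_id)
    hot_a <- a$label[match(donors, a$donor_id)] == "hot"
    hot_b <- b$label[match(donors, b$donor_id)] == "hot"
    tab <- matrix(c(sum(hot_a & hot_b), sum(hot_a & !hot_b),
                    sum(!hot_a & hot_b), sum(!hot_a & !hot_b)), 2, 2)
    degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    p <- if (degenerate) 1 else
      stats::fisher.test(tab, alternative = alternative)$p.value
    res[[j]] <- data.frame(tissue_a = ta, tissue_b = tb, n = length(donors),
                           n_hot_both = tab[1, 1], n_hot_a_only = tab[2, 1],
                           n_hot_b_only = tab[1, 2], n_neither = tab[2, 2],
                           p = p, degenerate = degenerate,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$threshold <- alpha / nrow(out)
  out$significant <- out$p < out$threshold
  out
}
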