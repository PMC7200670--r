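#' Build a synthetic signature set
#'
#' Creates pure cell-type expression profiles, a marker-gene signature
#' matrix, per-cell-type marker gene sets, and per-tissue background
#' profiles over a shared gene universe. Each cell type gets `n_markers`
#' dedicated marker genes whose expression is boosted by `marker_boost` in
#' that cell type and suppressed in the tissue backgrounds, which is what
#' makes both the constrained-regression and the rank-enrichment scorers
#' identifiable.
#'
#' @param cell_types Character vector of cell-type labels (>= 2).
#' @param tissues Character vector of tissue labels.
#' @param n_genes Total number of genes in the universe (markers included).
#' @param n_markers Marker genes per cell type (>= 2 recommended).
#' @param marker_boost Multiplicative marker expression boost in the owning
#'   cell type.
#' @param seed Integer seed.
#'
#' @return A list of class `"iqtl_signature"`: `profiles` (genes x cell
#'   types, full universe), `matrix` (marker genes x cell types, the
#'   deconvolution basis), `gene_sets` (named list of marker gene ids),
#'   `background` (genes x tissues).
#' @export
make_signature <- function(cell_types, tissues = "tissue1", n_genes = 600,
                           n_markers = 25, marker_boost = 30, seed = 1L) {
  stopifnot(length(cell_types) >= 2, n_markers >= 1)
  if (n_genes < length(cell_types) * n_markers + 50)
    stop("n_genes too small for the requested marker sets")
  set.seed(seed)

  genes <- sprintf("gene%05d", seq_len(n_genes))
  base <- stats::rlnorm(n_genes, meanlog = 3, sdlog = 1)
  names(base) <- genes

  k <- length(cell_types)
  gene_sets <- list()
  profiles <- matrix(0, n_genes, k, dimnames = list(genes, cell_types))
  for (j in seq_len(k)) {
    idx <- ((j - 1) * n_markers + 1):(j * n_markers)
    gene_sets[[cell_types[j]]] <- genes[idx]
    prof <- base * stats::rlnorm(n_genes, 0, 0.3)
    prof[idx] <- prof[idx] * marker_boost
    profiles[, j] <- prof
  }
  marker_idx <- seq_len(k * n_markers)
  # markers are near-absent in the immune-poor tissue backgrounds
  background <- matrix(0, n_genes, length(tissues),
                       dimnames = list(genes, tissues))
  for (t in seq_along(tissues)) {
    bg <- base * stats::rlnorm(n_genes, 0, 0.3)
    bg[marker_idx] <- bg[marker_idx] * 0.02
    background[, t] <- bg
  }
  structure(list(profiles = profiles,
                 matrix = profiles[marker_idx, , drop = FALSE],
                 gene_sets = gene_sets,
                 background = background),
            class = "iqtl_signature")
}

#' Synthesize bulk expression from a mixture design
#'
#' Linear expression-level mixing: for sample s in tissue t with cell-type
#' fractions f_c, `x_gs = (1 - sum(f)) * background_g(t) + sum_c f_c *
#' profile_gc`, multiplied by independent lognormal noise with coefficient
#' of variation `noise_cv` (unit mean). All values are non-negative by
#' construction.
#'
#' @param design An `iqtl_design` from [plant_effects()].
#' @param signature An `iqtl_signature` whose `background` covers every
#'   tissue in the design.
#' @param noise_cv Coefficient of variation of the multiplicative noise;
#'   0 gives the exact mixture.
#' @param seed Integer seed.
#' @return Genes x samples numeric matrix.
#' @export
synthesize_expression <- function(design, signature, noise_cv = 0.1,
                                  seed = 1L) {
  stopifnot(inherits(design, "iqtl_design"), inherits(signature, "iqtl_signature"))
  ct <- colnames(design$tissue_frac)
  if (!all(ct %in% colnames(signature$profiles)))
    stop("design cell types missing from the signature gene universe")
  miss_t <- setdiff(unique(design$samples$tissue), colnames(signature$background))
  if (length(miss_t)) stop("no background profile for tissue: ",
                           paste(miss_t, collapse = ", "))
  set.seed(seed)

  f <- design$tissue_frac
  bgw <- 1 - rowSums(f)
  prof <- signature$profiles[, ct, drop = FALSE]
  x <- prof %*% t(f) +
    signature$background[, design$samples$tissue, drop = FALSE] %*% diag(bgw, length(bgw))
  colnames(x) <- design$samples$sample_id
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    x <- x * matrix(stats::rlnorm(length(x), -sdlog^2 / 2, sdlog), nrow(x))
  }
  x
}

#' Generate an immune-spiked mixture panel
#'
#' Emulates a spike-in evaluation design at the expression level: a single
#' immune-poor tissue background is mixed with CD4 and CD8 T-cell profiles
#' in four design types -- CD4 only, CD8 only, both in equal proportions,
#' and both in unequal proportions (2:3 and 1:4) -- with total immune
#' content on a 5-20 percent grid. Each combination is emitted twice: a
#' homogeneous variant using one randomly chosen reference profile per cell
#' type and a heterogeneous variant averaging all supplied profiles.
#'
#' @param background Named non-negative vector: the tissue baseline.
#' @param cd4_profiles,cd8_profiles Matrix (genes x references) or single
#'   named vector of pure T-cell profiles on the same gene universe.
#' @param totals Total immune fraction grid.
#' @param noise_cv Multiplicative lognormal noise CV (0 = exact mixes).
#' @param seed Integer seed (profile choice for homogeneous mixes, noise).
#'
#' @return A list: `expression` (genes x mixes), `design` (an
#'   `iqtl_design` whose `samples` table carries `sim_type`,
#'   `heterogeneity` and `total` columns; `tissue_frac` and `immune_frac`
#'   have CD4/CD8 columns).
#' @export
spike_series <- function(background, cd4_profiles, cd8_profiles,
                         totals = c(0.05, 0.10, 0.15, 0.20),
                         noise_cv = 0, seed = 1L) {
  as_mat <- function(p) if (is.matrix(p)) p else matrix(p, ncol = 1,
                                                        dimnames = list(names(p), "ref1"))
  cd4 <- as_mat(cd4_profiles); cd8 <- as_mat(cd8_profiles)
  if (ncol(cd4) < 1 || ncol(cd8) < 1) stop("need at least one CD4 and one CD8 profile")
  set.seed(seed)

  types <- data.frame(
    sim_type = c("cd4_only", "cd8_only", "equal", "unequal_2_3", "unequal_1_4"),
    w_cd4 = c(1, 0, 0.5, 2 / 5, 1 / 5),
    w_cd8 = c(0, 1, 0.5, 3 / 5, 4 / 5),
    stringsAsFactors = FALSE
  )
  grid <- expand.grid(ti = seq_len(nrow(types)), total = totals,
                      heterogeneity = c("homogeneous", "heterogeneous"),
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  expr <- matrix(0, length(background), n,
                 dimnames = list(names(background), sprintf("mix%03d", seq_len(n))))
  f <- matrix(0, n, 2, dimnames = list(colnames(expr), c("CD4_T", "CD8_T")))
  for (i in seq_len(n)) {
    g <- grid[i, ]
    p4 <- if (g$heterogeneity == "homogeneous")
      cd4[, sample(ncol(cd4), 1)] else rowMeans(cd4)
    p8 <- if (g$heterogeneity == "homogeneous")
      cd8[, sample(ncol(cd8), 1)] else rowMeans(cd8)
    f4 <- g$total * types$w_cd4[g$ti]
    f8 <- g$total * types$w_cd8[g$ti]
    expr[, i] <- (1 - g$total) * background + f4 * p4 + f8 * p8
    f[i, ] <- c(f4, f8)
  }
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    expr <- expr * matrix(stats::rlnorm(length(expr), -sdlog^2 / 2, sdlog),
                          nrow(expr))
  }
  tot <- rowSums(f)
  rel <- f / ifelse(tot > 0, tot, 1)
  samples <- data.frame(sample_id = colnames(expr), donor_id = colnames(expr),
                        tissue = "mix", sim_type = types$sim_type[grid$ti],
                        heterogeneity = grid$heterogeneity, total = grid$total,
                        stringsAsFactors = FALSE)
  design <- structure(list(samples = samples, tissue_frac = f,
                           immune_frac = rel, effects = NULL,
                           noise_sd = 0, total_cap = 1, seed = seed),
                      class = "iqtl_design")
  list(expression = expr, design = design)
}
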