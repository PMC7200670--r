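#' Generate a synthetic donor cohort with tissue samples
#'
#' Draws a table of donors with the covariates used throughout the
#' association models (age bin, sex, death classification, autolysis score,
#' collection site) and assigns each donor a sample in each tissue
#' independently with the given per-tissue sampling rate. This emulates the
#' sparse donor-by-tissue sampling structure of large post-mortem expression
#' cohorts, where most donors contribute samples for only a subset of
#' tissues.
#'
#' @param n_donors Number of donors (>= 2).
#' @param tissues Character vector of tissue labels (at least one).
#' @param sampling_rate Probability that a given donor contributes a sample
#'   of a given tissue; scalar or vector recycled along `tissues`.
#' @param age_range Inclusive range of age bins; bins are multiples of 10.
#' @param sex_p Probability of sex `"F"`.
#' @param sites Collection-site labels sampled uniformly.
#' @param seed Integer seed; the same seed and arguments reproduce the
#'   cohort bit-exactly.
#'
#' @return A list of class `"iqtl_cohort"` with elements `donors` (one row
#'   per donor: `donor_id`, `age_bin`, `sex`, `death_class`, `autolysis`,
#'   `site`) and `samples` (one row per sample: `sample_id`, `donor_id`,
#'   `tissue`).
#' @export
generate_cohort <- function(n_donors, tissues, sampling_rate = 1,
                            age_range = c(20, 70), sex_p = 0.5,
                            sites = c("site1", "site2"), seed = 1L) {
  if (n_donors < 2) stop("n_donors must be >= 2")
  if (length(tissues) < 1) stop("at least one tissue is required")
  sampling_rate <- rep_len(sampling_rate, length(tissues))
  stopifnot(all(sampling_rate >= 0 & sampling_rate <= 1))
  set.seed(seed)

  bins <- seq(10 * ceiling(age_range[1] / 10), 10 * floor(age_range[2] / 10),
              by = 10)
  donors <- data.frame(
    donor_id = sprintf("D%04d", seq_len(n_donors)),
    age_bin = sample(bins, n_donors, replace = TRUE),
    sex = sample(c("F", "M"), n_donors, replace = TRUE,
                 prob = c(sex_p, 1 - sex_p)),
    death_class = sample(0:4, n_donors, replace = TRUE),
    autolysis = round(stats::runif(n_donors, 0, 3), 3),
    site = sample(sites, n_donors, replace = TRUE),
    stringsAsFactors = FALSE
  )

  samp <- list()
  for (ti in seq_along(tissues)) {
    take <- stats::runif(n_donors) <= sampling_rate[ti]
    if (any(take)) {
      samp[[ti]] <- data.frame(
        sample_id = paste0(donors$donor_id[take], "-", tissues[ti]),
        donor_id = donors$donor_id[take],
        tissue = tissues[ti],
        stringsAsFactors = FALSE
      )
    }
  }
  samples <- do.call(rbind, samp)
  rownames(samples) <- NULL
  structure(list(donors = donors, samples = samples), class = "iqtl_cohort")
}

#' Generate genotype dosages with block LD structure
#'
#' Simulates diploid dosages by drawing two haplotypes per donor. Variants
#' are organised in blocks: the first variant of a block is drawn at its own
#' allele frequency, and each subsequent variant copies the previous
#' variant's haplotypes, resampling each haplotype independently with
#' probability `recomb_prob`. `recomb_prob = 0` therefore yields perfect
#' within-block copies (pairwise r-squared of 1) and `recomb_prob = 1`
#' yields independent variants; intermediate values give decaying LD.
#' Missingness is introduced uniformly at random.
#'
#' Per-variant metadata (MAF, missing rate, Hardy-Weinberg P, LD partner
#' count at r-squared > 0.2) are recomputed from the emitted dosage matrix,
#' not copied from the generating parameters, so they stay self-consistent
#' under recomputation.
#'
#' @param donors Donor table (or an `iqtl_cohort`); only row count and
#'   donor ids are used.
#' @param n_variants Number of variants.
#' @param maf_range Interval within (0, 0.5] for the generating allele
#'   frequencies.
#' @param block_size Number of variants per LD block (>= 1).
#' @param recomb_prob Per-haplotype, per-site resampling probability in
#'   [0, 1].
#' @param missing_rate Probability an individual genotype is missing.
#' @param seed Integer seed.
#'
#' @return A list of class `"iqtl_genotypes"`: `dosage` (donors x variants
#'   integer matrix with entries 0/1/2/NA, donor ids as rownames) and
#'   `variants` (per-variant metadata: `variant_id`, `chrom`, `pos`, `maf`,
#'   `missing_rate`, `hwe_p`, `ld_partner_count`).
#' @seealso [variant_metadata()] for the recomputation used to fill the
#'   metadata columns.
#' @export
generate_genotypes <- function(donors, n_variants, maf_range = c(0.05, 0.5),
                               block_size = 10, recomb_prob = 0.1,
                               missing_rate = 0, seed = 1L) {
  if (inherits(donors, "iqtl_cohort")) donors <- donors$donors
  if (!(maf_range[1] > 0 && maf_range[2] <= 0.5 && maf_range[1] <= maf_range[2]))
    stop("maf_range must lie within (0, 0.5]")
  if (block_size < 1) stop("block_size must be >= 1")
  set.seed(seed)

  n <- nrow(donors)
  maf <- stats::runif(n_variants, maf_range[1], maf_range[2])
  h1 <- matrix(0L, n, n_variants)
  h2 <- matrix(0L, n, n_variants)
  for (v in seq_len(n_variants)) {
    new1 <- stats::rbinom(n, 1L, maf[v])
    new2 <- stats::rbinom(n, 1L, maf[v])
    if ((v - 1L) %% block_size == 0L) {  # block head
      h1[, v] <- new1
      h2[, v] <- new2
    } else {
      r1 <- stats::runif(n) < recomb_prob
      r2 <- stats::runif(n) < recomb_prob
      h1[, v] <- ifelse(r1, new1, h1[, v - 1L])
      h2[, v] <- ifelse(r2, new2, h2[, v - 1L])
    }
  }
  dos <- h1 + h2
  if (missing_rate > 0) {
    dos[stats::runif(n * n_variants) < missing_rate] <- NA_integer_
  }
  rownames(dos) <- donors$donor_id
  colnames(dos) <- sprintf("rs%06d", seq_len(n_variants))

  meta <- variant_metadata(dos)
  meta$chrom <- "1"
  meta$pos <- 10000L * seq_len(n_variants)
  meta <- meta[, c("variant_id", "chrom", "pos", "maf", "missing_rate",
                   "hwe_p", "ld_partner_count")]
  structure(list(dosage = dos, variants = meta), class = "iqtl_genotypes")
}

#' Recompute per-variant metadata from a dosage matrix
#'
#' MAF is the folded allele frequency from non-missing genotypes;
#' the Hardy-Weinberg P-value is the 1-df chi-square test without
#' continuity correction on the non-missing genotype counts; the LD
#' partner count is the number of other variants with squared Pearson
#' correlation above `r2_threshold`, computed on the mean-imputed dosages.
#'
#' @param dosage Donors x variants matrix with entries 0/1/2/NA.
#' @param r2_threshold r-squared cutoff defining an LD partner.
#' @return data.frame with `variant_id`, `maf`, `missing_rate`, `hwe_p`,
#'   `ld_partner_count`.
#' @export
variant_metadata <- function(dosage, r2_threshold = 0.2) {
  n <- nrow(dosage)
  miss <- colMeans(is.na(dosage))
  p_alt <- colMeans(dosage, na.rm = TRUE) / 2
  p_alt[is.nan(p_alt)] <- 0
  maf <- pmin(p_alt, 1 - p_alt)

  hwe <- apply(dosage, 2, function(g) {
    g <- g[!is.na(g)]
    hwe_pvalue(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  })

  # mean imputation keeps the r2 computation a single BLAS call
  imp <- dosage
  if (anyNA(imp)) {
    cm <- colMeans(imp, na.rm = TRUE)
    idx <- which(is.na(imp), arr.ind = TRUE)
    imp[idx] <- cm[idx[, 2]]
  }
  sds <- apply(imp, 2, stats::sd)
  ld_count <- integer(ncol(imp))
  ok <- sds > 0
  if (sum(ok) >= 2) {
    r2 <- stats::cor(imp[, ok, drop = FALSE])^2
    diag(r2) <- 0
    ld_count[ok] <- as.integer(rowSums(r2 > r2_threshold))
  }
  data.frame(variant_id = colnames(dosage), maf = maf, missing_rate = miss,
             hwe_p = hwe, ld_partner_count = ld_count,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Plant demographic and genetic effects on cell-type fractions
#'
#' Generates ground-truth cell-type fractions for every sample of a cohort
#' through an inverse-logit of a linear predictor in standardized
#' covariates: for each cell type c,
#' `f_c = plogis(qlogis(base_c) + beta_age * age_z + beta_sex * sex_c +
#' beta_snp * dosage_z + N(0, noise_sd))`, where `age_z` and `dosage_z` are
#' standardized and `sex_c` is a centered 0/1 indicator (1 = F). Per-sample
#' fractions are then rescaled so their sum does not exceed `total_cap`.
#' The planted effect sizes are recorded in the returned design so that
#' downstream scans can be checked against a known truth.
#'
#' @param cohort An `iqtl_cohort`.
#' @param genotypes An `iqtl_genotypes` (only needed when any `snp_id` is
#'   set).
#' @param effect_spec data.frame with one row per cell type: `cell_type`,
#'   `base` (baseline fraction in (0, 1)), `beta_age`, `beta_sex`,
#'   `beta_snp`, `snp_id` (NA when no genetic effect is planted).
#' @param noise_sd Gaussian noise SD on the logit scale.
#' @param total_cap Maximum allowed total immune fraction per sample, in
#'   (0, 1].
#' @param seed Integer seed.
#'
#' @return A list of class `"iqtl_design"`: `samples` (the cohort sample
#'   map), `tissue_frac` (samples x cell types matrix of fractions of the
#'   whole sample), `immune_frac` (fractions of the immune compartment,
#'   rows summing to 1 wherever total immune content is positive),
#'   `effects` (the effect_spec), `noise_sd`, `total_cap`, `seed`.
#' @export
plant_effects <- function(cohort, genotypes = NULL, effect_spec,
                          noise_sd = 0, total_cap = 0.6, seed = 1L) {
  stopifnot(inherits(cohort, "iqtl_cohort"))
  if (!(total_cap > 0 && total_cap <= 1)) stop("total_cap must be in (0, 1]")
  need <- c("cell_type", "base", "beta_age", "beta_sex", "beta_snp")
  stopifnot(all(need %in% names(effect_spec)))
  if (is.null(effect_spec$snp_id)) effect_spec$snp_id <- NA_character_
  set.seed(seed)

  samples <- cohort$samples
  donors <- cohort$donors
  di <- match(samples$donor_id, donors$donor_id)
  age_z <- as.numeric(scale(donors$age_bin[di]))
  if (all(is.nan(age_z))) age_z <- rep(0, nrow(samples))
  sex_c <- (donors$sex[di] == "F") - mean(donors$sex[di] == "F")

  k <- nrow(effect_spec)
  f <- matrix(0, nrow(samples), k,
              dimnames = list(samples$sample_id, effect_spec$cell_type))
  for (j in seq_len(k)) {
    eta <- stats::qlogis(effect_spec$base[j]) +
      effect_spec$beta_age[j] * age_z + effect_spec$beta_sex[j] * sex_c
    sid <- effect_spec$snp_id[j]
    if (!is.na(sid) && effect_spec$beta_snp[j] != 0) {
      if (is.null(genotypes) || !(sid %in% colnames(genotypes$dosage)))
        stop("unknown target SNP: ", sid)
      dos <- genotypes$dosage[samples$donor_id, sid]
      dos[is.na(dos)] <- mean(dos, na.rm = TRUE)
      dz <- if (stats::sd(dos) > 0) as.numeric(scale(dos)) else rep(0, length(dos))
      eta <- eta + effect_spec$beta_snp[j] * dz
    }
    if (noise_sd > 0) eta <- eta + stats::rnorm(nrow(samples), 0, noise_sd)
    f[, j] <- stats::plogis(eta)
  }
  tot <- rowSums(f)
  over <- tot > total_cap
  if (any(over)) f[over, ] <- f[over, , drop = FALSE] * (total_cap / tot[over])

  tot <- rowSums(f)
  rel <- f
  pos <- tot > 0
  rel[pos, ] <- f[pos, , drop = FALSE] / tot[pos]
  rel[!pos, ] <- 0

  structure(list(samples = samples, tissue_frac = f, immune_frac = rel,
                 effects = effect_spec, noise_sd = noise_sd,
                 total_cap = total_cap, seed = seed),
            class = "iqtl_design")
}

#' Generate a synthetic variant annotation table
#'
#' Flags each variant as a (per-tissue) eQTL with probability
#' `plogis(qlogis(base_rate) + maf_bias * (maf - mean(maf)))`, so a
#' positive `maf_bias` makes common variants more likely to carry the flag
#' (a deliberately plantable confounder for the matched-permutation null).
#' Catalog flags (prior GWAS association) are independent at
#' `catalog_rate`.
#'
#' @param genotypes An `iqtl_genotypes`, or a variant metadata data.frame
#'   with `variant_id`, `maf` and `ld_partner_count` columns.
#' @param tissues Tissue labels for which eQTL flags are drawn.
#' @param base_rate Baseline eQTL flag probability in [0, 1].
#' @param maf_bias Log-odds slope of the flag probability on centered MAF.
#' @param catalog_rate Catalog flag probability in [0, 1].
#' @param seed Integer seed.
#'
#' @return data.frame with `variant_id`, `maf`, `ld_partner_count`, one
#'   logical `eqtl_<tissue>` column per tissue, and `catalog_flag`.
#' @export
generate_annotation <- function(genotypes, tissues = "tissue1",
                                base_rate = 0.1, maf_bias = 0,
                                catalog_rate = 0.05, seed = 1L) {
  meta <- if (inherits(genotypes, "iqtl_genotypes")) genotypes$variants else genotypes
  stopifnot(all(c("variant_id", "maf", "ld_partner_count") %in% names(meta)))
  stopifnot(base_rate >= 0, base_rate <= 1,
            catalog_rate >= 0, catalog_rate <= 1)
  set.seed(seed)

  nv <- nrow(meta)
  ann <- data.frame(variant_id = meta$variant_id, maf = meta$maf,
                    ld_partner_count = meta$ld_partner_count,
                    stringsAsFactors = FALSE)
  prob <- if (base_rate %in% c(0, 1)) rep(base_rate, nv) else
    stats::plogis(stats::qlogis(base_rate) + maf_bias * (meta$maf - mean(meta$maf)))
  for (ti in tissues) {
    ann[[paste0("eqtl_", ti)]] <- stats::runif(nv) < prob
  }
  ann$catalog_flag <- stats::runif(nv) < catalog_rate
  ann
}
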