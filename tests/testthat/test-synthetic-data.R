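test_that("cohort generation is reproducible and counts samples correctly", {
  a <- generate_cohort(10, c("a", "b", "c"), sampling_rate = 1, seed = 42)
  b <- generate_cohort(10, c("a", "b", "c"), sampling_rate = 1, seed = 42)
  expect_identical(a, b)
  expect_equal(nrow(a$samples), 30)
  expect_true(all(table(a$samples$donor_id) == 3))
  expect_true(all(a$donors$age_bin %% 10 == 0))
  expect_true(all(a$donors$death_class %in% 0:4))

  expect_error(generate_cohort(1, "a"), "n_donors")
  expect_error(generate_cohort(5, character(0)), "tissue")
})

test_that("cohort sex balance stays inside the exact binomial interval", {
  co <- generate_cohort(500, "a", sex_p = 0.5, seed = 7)
  n_f <- sum(co$donors$sex == "F")
  ci <- stats::qbinom(c(0.005, 0.995), 500, 0.5)
  expect_gte(n_f, ci[1])
  expect_lte(n_f, ci[2])
})

test_that("genotype LD structure follows the block-copy model", {
  co <- fixture_cohort(500, "a", seed = 1)
  # recomb 0: perfect copies within a block
  g0 <- generate_genotypes(co, 20, block_size = 5, recomb_prob = 0,
                           seed = 2)
  for (blk in split(1:20, rep(1:4, each = 5))) {
    expect_true(all(g0$dosage[, blk] == g0$dosage[, blk[1]]))
  }
  r2_0 <- stats::cor(g0$dosage[, 1:5])^2
  expect_true(all(abs(r2_0 - 1) < 1e-12))

  # recomb 1: independent variants, mean off-diagonal r2 near 0
  g1 <- generate_genotypes(co, 40, block_size = 5, recomb_prob = 1,
                           seed = 3)
  r2 <- stats::cor(g1$dosage)^2
  expect_lt(mean(r2[upper.tri(r2)]), 0.02)

  expect_error(generate_genotypes(co, 10, maf_range = c(0, 0.6)),
               "maf_range")
})

test_that("genotype missingness and metadata are self-consistent", {
  co <- fixture_cohort(200, "a", seed = 1)
  g <- generate_genotypes(co, 200, missing_rate = 0.1, seed = 4)
  obs <- mean(is.na(g$dosage))
  ci <- stats::qbinom(c(0.005, 0.995), 200 * 200, 0.1) / (200 * 200)
  expect_gte(obs, ci[1])
  expect_lte(obs, ci[2])
  # metadata recomputation is idempotent
  re <- variant_metadata(g$dosage)
  expect_equal(re$maf, g$variants$maf)
  expect_equal(re$hwe_p, g$variants$hwe_p)
  expect_equal(re$ld_partner_count, g$variants$ld_partner_count)
})

test_that("planted effects shape the fraction model as specified", {
  co <- fixture_cohort(500, "a", seed = 11)
  g <- generate_genotypes(co, 20, block_size = 1, seed = 12)
  spec <- null_effect_spec()

  # no effects, no noise: all samples identical
  d0 <- plant_effects(co, g, spec, noise_sd = 0, seed = 13)
  expect_true(all(apply(d0$tissue_frac, 2, function(x) diff(range(x))) == 0))

  # positive SNP effect: strictly increasing dosage-group means
  spec2 <- spec
  spec2$beta_snp[spec2$cell_type == "CD8_T"] <- 0.8
  spec2$snp_id[spec2$cell_type == "CD8_T"] <- "rs000005"
  d2 <- plant_effects(co, g, spec2, noise_sd = 0.2, seed = 14)
  dos <- g$dosage[d2$samples$donor_id, "rs000005"]
  mns <- tapply(d2$tissue_frac[, "CD8_T"], dos, mean)
  expect_true(all(diff(mns[as.character(0:2)]) > 0))

  # truth scenarios are mutually consistent
  tot <- rowSums(d2$tissue_frac)
  pos <- tot > 0
  expect_equal(d2$immune_frac[pos, ],
               d2$tissue_frac[pos, ] / tot[pos], tolerance = 1e-12)
  expect_true(all(abs(rowSums(d2$immune_frac[pos, ]) - 1) < 1e-9))
  expect_true(all(tot <= d2$total_cap + 1e-12))

  expect_error(plant_effects(co, g, within(spec2, snp_id[3] <- "rsXXX"),
                             seed = 1), "unknown target SNP")
})

test_that("null age associations reject at the nominal 5% rate", {
  # no planted effects: slope t-test on age exceeds |t| > 2 in ~5% of reps
  spec <- null_effect_spec()
  hits <- vapply(1:200, function(r) {
    co <- generate_cohort(100, "a", seed = 1000 + r)
    d <- plant_effects(co, NULL, spec, noise_sd = 0.4, seed = 2000 + r)
    age <- co$donors$age_bin[match(d$samples$donor_id, co$donors$donor_id)]
    fit <- summary(stats::lm(d$tissue_frac[, "CD8_T"] ~ age))$coefficients
    abs(fit[2, 3]) > 2
  }, logical(1))
  rate <- mean(hits)
  ci <- stats::qbinom(c(0.005, 0.995), 200, 0.05) / 200
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("expression synthesis is an exact linear mixture at zero noise", {
  sig <- fixture_signature()
  co <- fixture_cohort(6, "colon", seed = 2)

  d0 <- plant_effects(co, NULL, null_effect_spec(base = 1e-6),
                      noise_sd = 0, seed = 1)
  d0$tissue_frac[] <- 0
  d0$immune_frac[] <- 0
  x0 <- synthesize_expression(d0, sig, noise_cv = 0, seed = 1)
  expect_equal(unname(x0[, 1]), unname(sig$background[, "colon"]))

  # pure sample equals the signature column
  d1 <- d0
  d1$total_cap <- 1
  d1$tissue_frac[, "CD8_T"] <- 1
  x1 <- synthesize_expression(d1, sig, noise_cv = 0, seed = 1)
  expect_equal(unname(x1[, 1]), unname(sig$profiles[, "CD8_T"]))

  # 50/50 mixture of two pure types is the average of the two columns
  d2 <- d0
  d2$tissue_frac[, c("B", "NK")] <- 0.5
  x2 <- synthesize_expression(d2, sig, noise_cv = 0, seed = 1)
  expect_equal(unname(x2[, 1]),
               unname((sig$profiles[, "B"] + sig$profiles[, "NK"]) / 2))
  expect_true(all(synthesize_expression(d2, sig, noise_cv = 0.2, seed = 2) >= 0))
})

test_that("spike series emits the four design types on the 5-20% grid", {
  sig <- fixture_signature()
  cd4 <- fixture_tcell_profiles(sig, "CD4_naive")
  cd8 <- fixture_tcell_profiles(sig, "CD8_T")
  sp <- spike_series(sig$background[, "colon"], cd4, cd8, seed = 1)
  d <- sp$design$samples

  expect_setequal(unique(d$sim_type),
                  c("cd4_only", "cd8_only", "equal", "unequal_2_3",
                    "unequal_1_4"))
  expect_setequal(unique(d$total), c(0.05, 0.10, 0.15, 0.20))
  expect_setequal(unique(d$heterogeneity),
                  c("homogeneous", "heterogeneous"))

  eq <- d$sim_type == "equal"
  expect_equal(sp$design$tissue_frac[eq, "CD4_T"],
               sp$design$tissue_frac[eq, "CD8_T"])
  cd4only <- d$sim_type == "cd4_only"
  expect_true(all(sp$design$immune_frac[cd4only, "CD4_T"] == 1))
  i14 <- which(d$sim_type == "unequal_1_4" & d$total == 0.10)
  expect_equal(unname(sp$design$tissue_frac[i14, "CD4_T"]),
               rep(0.02, length(i14)))
  expect_equal(unname(sp$design$tissue_frac[i14, "CD8_T"]),
               rep(0.08, length(i14)))
  expect_error(spike_series(sig$background[, 1], cd4[, 0], cd8),
               "at least one")
})

test_that("annotation flags follow the base rate and MAF bias", {
  co <- fixture_cohort(80, "a", seed = 1)
  g <- generate_genotypes(co, 5000, block_size = 1, seed = 2)
  a1 <- generate_annotation(g, "a", base_rate = 1, seed = 3)
  expect_true(all(a1$eqtl_a))
  a0 <- generate_annotation(g, "a", base_rate = 0, seed = 3)
  expect_false(any(a0$eqtl_a))
  ab <- generate_annotation(g, "a", base_rate = 0.3, maf_bias = 8, seed = 4)
  fit <- stats::glm(ab$eqtl_a ~ ab$maf, family = stats::binomial())
  expect_gt(stats::coef(fit)[2], 0)
})

test_that("null synthetic data give uniform scan P-values", {
  # zero planted effects (noise present): scan P ~ Uniform(0,1)
  spec <- null_effect_spec()
  ps <- vapply(1:200, function(r) {
    co <- generate_cohort(60, "a", seed = 300 + r)
    g <- generate_genotypes(co, 1, block_size = 1, seed = 400 + r)
    d <- plant_effects(co, g, spec, noise_sd = 0.4, seed = 500 + r)
    z <- rank_inverse_normal(d$tissue_frac[, "B"])
    names(z) <- d$samples$donor_id
    snp_scan(z, g)$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
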