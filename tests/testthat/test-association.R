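test_that("HWE chi-square matches the closed-form determinant identity", {
  # worked example: (50, 0, 50) gives chi-square = n = 100
  p <- hwe_pvalue(50, 0, 50)
  expect_equal(p, stats::pchisq(100, 1, lower.tail = FALSE))
  expect_lt(p, 1e-6)

  for (n0 in c(0, 3, 10, 40)) {
    for (n1 in c(0, 5, 25)) {
      for (n2 in c(1, 8, 30)) {
        if (n0 + n1 + n2 < 3) next
        expect_equal(hwe_pvalue(n0, n1, n2), hwe_oracle(n0, n1, n2),
                     tolerance = 1e-12)
      }
    }
  }
  expect_equal(hwe_pvalue(10, 0, 0), 1)  # monomorphic
})

test_that("genotype QC enforces strict printed thresholds", {
  dos <- cbind(
    mono = rep(0L, 1000),                           # maf 0: removed
    ok = rep(c(0L, 1L, 2L, 1L), 250),               # clean: kept
    hwe = rep(c(0L, 2L), 500),                      # no hets: removed
    m10 = rep(c(0L, 1L, 2L, 1L), 250),              # missing 0.10: kept
    m101 = rep(c(0L, 1L, 2L, 1L), 250))             # missing 0.101: removed
  dos[1:100, "m10"] <- NA
  dos[1:101, "m101"] <- NA
  rownames(dos) <- paste0("d", 1:1000)
  g <- structure(list(dosage = dos,
                      variants = data.frame(variant_id = colnames(dos))),
                 class = "iqtl_genotypes")
  qc <- qc_genotypes(g)
  expect_setequal(colnames(qc$genotypes$dosage), c("ok", "m10"))
  expect_setequal(qc$removed$variant_id, c("mono", "hwe", "m101"))
  expect_equal(qc$removed$reason[qc$removed$variant_id == "mono"], "maf")
  expect_equal(qc$removed$reason[qc$removed$variant_id == "m101"],
               "missingness")
  expect_equal(qc$removed$reason[qc$removed$variant_id == "hwe"], "hwe")
})

test_that("residualization projects out covariates before rank-normalizing", {
  set.seed(15)
  n <- 41
  cov <- data.frame(age_bin = sample(seq(20, 70, 10), n, TRUE),
                    sex = sample(c("F", "M"), n, TRUE),
                    death_class = sample(0:2, n, TRUE),
                    autolysis = stats::runif(n),
                    site = sample(c("a", "b"), n, TRUE))
  X <- covariate_design(cov)
  y <- 0.03 * cov$age_bin + drop(X %*% stats::rnorm(ncol(X), 0, 0.1))
  res <- stats::lm.fit(X, y)$residuals
  # planted age effect is exactly removed (OLS projection)
  expect_lt(abs(stats::coef(stats::lm(res ~ cov$age_bin))[2]), 1e-10)

  z <- adjust_and_transform(y + stats::rnorm(n, 0, 0.2), X)
  expect_equal(unname(sort(z)), stats::qnorm((seq_len(n) - 0.5) / n))
})

test_that("the median residual of an odd-length sample maps to zero", {
  set.seed(16)
  n <- 25
  cov <- data.frame(age_bin = sample(seq(20, 70, 10), n, TRUE),
                    sex = sample(c("F", "M"), n, TRUE),
                    death_class = sample(0:2, n, TRUE),
                    autolysis = stats::runif(n),
                    site = sample(c("a", "b"), n, TRUE))
  X <- covariate_design(cov)
  z <- adjust_and_transform(stats::rnorm(n), X)
  expect_equal(unname(sort(z)[(n + 1) / 2]), 0)
})

test_that("snp_scan matches closed-form least squares", {
  # 5-point worked dataset against lm
  g5 <- matrix(c(0, 1, 2, 1, 0), 5, 1,
               dimnames = list(paste0("d", 1:5), "v1"))
  z5 <- stats::setNames(c(0.2, 1.1, 2.3, 0.9, -0.1), rownames(g5))
  sc <- snp_scan(z5, g5, min_n = 2)
  fit <- summary(stats::lm(z5 ~ g5[, 1]))$coefficients
  expect_equal(sc$slope, fit[2, 1], tolerance = 1e-10)
  expect_equal(sc$se, fit[2, 2], tolerance = 1e-10)
  expect_equal(sc$p, fit[2, 4], tolerance = 1e-10)

  # larger scan with missingness, pairwise deletion, against lm per SNP
  set.seed(17)
  n <- 80
  G <- matrix(stats::rbinom(n * 10, 2, 0.3), n, 10,
              dimnames = list(paste0("d", 1:n), paste0("v", 1:10)))
  G[sample(length(G), 40)] <- NA
  z <- stats::setNames(stats::rnorm(n), rownames(G))
  sc2 <- snp_scan(z, G)
  for (j in 1:10) {
    fit <- summary(stats::lm(z ~ G[, j]))$coefficients
    expect_equal(sc2$slope[j], fit[2, 1], tolerance = 1e-10)
    expect_equal(sc2$p[j], fit[2, 4], tolerance = 1e-10)
  }

  # perfect association
  gp <- matrix(rep(0:2, length.out = 30), 30, 1,
               dimnames = list(paste0("d", 1:30), "v"))
  zp <- stats::setNames(as.numeric(scale(gp[, 1])), rownames(gp))
  scp <- snp_scan(zp, gp)
  expect_lt(scp$p, 1e-200)
  expect_equal(scp$slope, 1 / stats::sd(gp[, 1]), tolerance = 1e-12)

  # zero-variance single variant errors
  g0 <- matrix(1L, 20, 1, dimnames = list(paste0("d", 1:20), "v"))
  expect_error(snp_scan(stats::setNames(stats::rnorm(20), rownames(g0)), g0),
               "variance")
})

test_that("snp_scan P-values are uniform under the null", {
  set.seed(18)
  n <- 100
  G <- matrix(stats::rbinom(n * 500, 2, 0.3), n, 500,
              dimnames = list(paste0("d", 1:n), paste0("v", 1:500)))
  z <- stats::setNames(stats::rnorm(n), rownames(G))
  ps <- snp_scan(z, G)$p
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("age and sex coefficients come from the full multiple regression", {
  set.seed(19)
  n <- 120
  cov <- data.frame(age_bin = sample(seq(20, 70, 10), n, TRUE),
                    sex = sample(c("F", "M"), n, TRUE),
                    death_class = sample(0:4, n, TRUE),
                    autolysis = stats::runif(n),
                    site = sample(c("a", "b", "c"), n, TRUE))
  y <- 0.01 * cov$age_bin + stats::rnorm(n, 0, 0.001)
  out <- age_sex_scan(y, cov)
  expect_lt(out$p[out$term == "age"], 1e-100)
  expect_gt(out$p[out$term == "sex"], 0.001)

  # coefficients match a matrix-algebra least-squares oracle on 12 rows
  cov12 <- cov[1:12, ]
  cov12$death_class <- 0; cov12$site <- "a"    # avoid empty levels
  y12 <- stats::rnorm(12)
  out12 <- age_sex_scan(y12, cov12)
  X <- covariate_design(cov12)
  beta <- solve(crossprod(X), crossprod(X, y12))
  expect_equal(out12$slope[out12$term == "age"],
               unname(beta["age_bin", 1]), tolerance = 1e-10)

  # sex-balanced null is calibrated
  ps <- vapply(1:200, function(r) {
    set.seed(300 + r)
    cv <- data.frame(age_bin = sample(seq(20, 70, 10), 60, TRUE),
                     sex = rep(c("F", "M"), 30),
                     death_class = sample(0:2, 60, TRUE),
                     autolysis = stats::runif(60),
                     site = sample(c("a", "b"), 60, TRUE))
    out <- age_sex_scan(stats::rnorm(60), cv)
    out$p[out$term == "sex"]
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Brown combination has the documented limits and guards", {
  set.seed(20)
  x <- stats::rnorm(300)
  y <- stats::rnorm(300)
  z <- stats::rnorm(300)

  expect_equal(ebm_combine(c(1, 1, 1), rbind(x, y, z)), 1)
  expect_error(ebm_combine(0.5, matrix(1:10, 1)), "at least two")
  expect_error(ebm_combine(c(0, 0.5), rbind(x, y)), "\\(0, 1\\]")
  expect_error(ebm_combine(c(0.5, 0.5), rbind(x, rep(1, 300))),
               "degenerate")

  # affine invariance of the empirical covariance machinery
  p3 <- c(0.03, 0.2, 0.4)
  expect_equal(ebm_combine(p3, rbind(x, y, z)),
               ebm_combine(p3, rbind(5 + 2 * x, y, z)))

  # perfectly correlated limit returns (about) the shared P
  for (p in c(0.02, 0.2, 0.6)) {
    expect_equal(ebm_combine(rep(p, 3), rbind(x, x, x)), p,
                 tolerance = 0.06)
  }

  # zero-covariance closed form is exactly Fisher
  X_stat <- -2 * 3 * log(0.05)
  expect_equal(brown_combine(c(0.05, 0.05, 0.05), 0),
               stats::pchisq(X_stat, df = 6, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("BH adjustment is the standard step-up with monotonicity", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(22)
  p <- stats::runif(50)
  adj <- bh_fdr(p)
  expect_false(is.unsorted(adj[order(p)]))
  expect_equal(adj, stats::p.adjust(p, "BH"))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("significance tiers use strict inequalities", {
  rec <- data.frame(combined_p = c(5e-8, 4.9e-8, 1e-5, 9.9e-6),
                    fdr = c(0.099, 0.1, 0.5, 0.01))
  out <- significance_calls(rec)
  expect_equal(out$genome_wide, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$suggested, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(out$fdr_significant, c(TRUE, FALSE, FALSE, TRUE))
})
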