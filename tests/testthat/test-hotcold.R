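test_that("consensus clustering separates planted groups and is seeded", {
  set.seed(41)
  x <- c(stats::rnorm(50, -5, 0.5), stats::rnorm(50, 5, 0.5))
  names(x) <- paste0("s", 1:100)
  c1 <- consensus_kmeans(x, k_range = 2:4, n_resample = 100, nstart = 3,
                         seed = 2)
  c2 <- consensus_kmeans(x, k_range = 2:4, n_resample = 100, nstart = 3,
                         seed = 2)
  expect_identical(c1, c2)

  M <- c1$runs[["2"]]$M
  expect_true(isSymmetric(M))
  expect_true(all(diag(M) == 1))
  off <- M[upper.tri(M)]
  expect_gte(mean(off < 0.05 | off > 0.95), 0.99)

  # samples with identical scores always co-cluster
  expect_equal(M["s1", "s2"], 1, tolerance = 0.05)
  expect_error(consensus_kmeans(rep(1, 30), 2:3, 10), "constant")
  expect_error(consensus_kmeans(x[1:3], 2:4, 10), "more samples")
})

test_that("the delta-area rule picks the planted number of clusters", {
  set.seed(42)
  for (g in 2:3) {
    x <- as.numeric(sapply(seq_len(g), function(i)
      stats::rnorm(50, 10 * i, 0.5)))
    names(x) <- paste0("s", seq_along(x))
    cons <- consensus_kmeans(x, k_range = 2:5, n_resample = 100,
                             nstart = 3, seed = g)
    expect_equal(select_k(cons)$k, g)
  }
})

test_that("consensus CDF matches direct pair counting on hand matrices", {
  M <- diag(3)
  M[1, 2] <- M[2, 1] <- 0.2
  M[1, 3] <- M[3, 1] <- 0.6
  M[2, 3] <- M[3, 2] <- 1.0
  expect_equal(consensus_cdf(M, 0.5), 1 / 3)
  expect_equal(consensus_cdf(M, c(0, 0.2, 0.6, 1)),
               c(0, 1 / 3, 2 / 3, 1))

  # saturated matrix: CDF identically 1, area 1
  M1 <- diag(4)  # all off-diagonal 0 <= c for every grid point
  grid <- seq(0, 1, by = 0.01)
  expect_true(all(consensus_cdf(M1, grid) == 1))
  area <- sum(diff(grid) * consensus_cdf(M1, grid)[-1])
  expect_equal(area, 1)

  # 4x4 hand matrix against brute-force counting over the 6 pairs
  set.seed(43)
  vals <- stats::runif(6)
  M2 <- diag(4)
  M2[upper.tri(M2)] <- vals
  M2[lower.tri(M2)] <- t(M2)[lower.tri(M2)]
  for (c in c(0.1, 0.5, 0.9)) {
    expect_equal(consensus_cdf(M2, c), mean(vals <= c))
  }
})

test_that("hot/cold labelling follows cluster means with stable ties", {
  scores <- c(0.1, 0.12, 0.5, 0.52, 0.9, 0.95)
  lab3 <- label_hot_cold(c(1, 1, 2, 2, 3, 3), scores)
  expect_equal(lab3, c("cold", "cold", "intermediate", "intermediate",
                       "hot", "hot"))
  lab2 <- label_hot_cold(c(1, 1, 1, 2, 2, 2), scores)
  expect_false(any(lab2 == "intermediate"))
  # exact mean tie breaks toward the smaller cluster index
  tie <- label_hot_cold(c(1, 2, 3), c(0.5, 0.5, 0.1))
  expect_equal(tie, c("hot", "intermediate", "cold"))
  expect_error(label_hot_cold(rep(1, 5), stats::runif(5)), "two clusters")
})

test_that("quintile labels use nearest-rank cuts and nest across q", {
  x <- stats::setNames(seq_len(100) + 0.5, paste0("s", 1:100))
  same <- list(x, x * 2, x + 10)  # identical rankings
  lab <- quintile_labels(same, q = 0.2)
  expect_equal(sum(lab == "hot"), 20)
  expect_equal(sum(lab == "cold"), 20)

  flipped <- list(x, x, stats::setNames(rev(x), names(x)))
  labf <- quintile_labels(flipped, q = 0.2)
  expect_equal(sum(labf == "hot"), 0)

  lab4 <- quintile_labels(same, q = 0.4)
  expect_true(all(names(lab)[lab == "hot"] %in%
                    names(lab4)[lab4 == "hot"]))
})

test_that("consensus across methods is an order-invariant intersection", {
  l1 <- stats::setNames(c("hot", "hot", "cold", "intermediate"),
                        paste0("s", 1:4))
  l2 <- stats::setNames(c("hot", "intermediate", "cold", "cold"),
                        paste0("s", 1:4))
  l3 <- stats::setNames(c("hot", "hot", "cold", "cold"), paste0("s", 1:4))
  cs <- consensus_across_methods(list(l1, l2, l3))
  expect_equal(cs$hot, "s1")
  expect_setequal(cs$cold, "s3")
  expect_equal(consensus_across_methods(list(l3, l2, l1))$hot, cs$hot)
  expect_equal(consensus_across_methods(list(l1, l1, l1))$hot,
               names(l1)[l1 == "hot"])
  # disjoint hot sets give an empty consensus, bounded by the minimum
  l4 <- stats::setNames(c("cold", "cold", "hot", "hot"), paste0("s", 1:4))
  expect_length(consensus_across_methods(list(l1, l4))$hot, 0)
  expect_lte(length(cs$hot),
             min(lengths(lapply(list(l1, l2, l3),
                                function(l) which(l == "hot")))))
})

test_that("hot burden restricts to well-sampled donors and finds the mode", {
  lab <- data.frame(
    donor_id = rep(c("d1", "d2", "d3", "d4", "d5"), each = 10),
    tissue = rep(paste0("t", 1:10), 5),
    label = "intermediate", stringsAsFactors = FALSE)
  lab$label[lab$donor_id == "d2"][1] <- "hot"
  lab$label[lab$donor_id == "d3"][1:2] <- "hot"
  lab$label[lab$donor_id == "d4"][1] <- "hot"
  lab7 <- lab[!(lab$donor_id == "d5" & lab$tissue %in% paste0("t", 8:10)), ]
  hb <- hot_burden(lab7, min_tissues = 8)
  expect_false("d5" %in% hb$per_donor$donor_id)  # only 7 tissues
  expect_equal(hb$per_donor$fraction[hb$per_donor$donor_id == "d1"], 0)
  expect_equal(hb$mode_hot, 1)  # counts 0,1,2,1 -> mode 1
})

test_that("hot-sharing Fisher test matches hypergeometric enumeration", {
  mk_labels <- function(a, b, c, d) {
    n <- a + b + c + d
    donors <- paste0("d", seq_len(n))
    hot_a <- c(rep(TRUE, a + b), rep(FALSE, c + d))
    hot_b <- c(rep(TRUE, a), rep(FALSE, b), rep(TRUE, c), rep(FALSE, d))
    rbind(data.frame(donor_id = donors, tissue = "t1",
                     label = ifelse(hot_a, "hot", "intermediate")),
          data.frame(donor_id = donors, tissue = "t2",
                     label = ifelse(hot_b, "hot", "intermediate")))
  }
  # balanced table has P = 1
  res <- hot_sharing_test(mk_labels(5, 5, 5, 5))
  expect_equal(res$p, 1, tolerance = 1e-12)
  expect_equal(res$threshold, 0.05)

  # degenerate margin is logged with P = 1
  resd <- hot_sharing_test(mk_labels(0, 0, 5, 5))
  expect_true(resd$degenerate)
  expect_equal(resd$p, 1)

  # sweep of tables with margins <= 12 against the enumeration oracle
  for (a in c(0, 1, 3, 6)) for (b in c(0, 2, 6)) {
    for (c_ in c(1, 4)) for (d in c(0, 3, 6)) {
      if (a + b == 0 || c_ + d == 0 || a + c_ == 0 || b + d == 0) next
      got <- hot_sharing_test(mk_labels(a, b, c_, d))$p
      expect_equal(got, fisher_oracle(a, b, c_, d), tolerance = 1e-10)
    }
  }
})

test_that("independent hot labels keep the Fisher test conservative", {
  set.seed(44)
  all_p <- numeric(0)
  family_reject <- vapply(1:200, function(r) {
    lab <- do.call(rbind, lapply(1:5, function(t)
      data.frame(donor_id = paste0("d", 1:40), tissue = paste0("t", t),
                 label = sample(c("hot", "intermediate"), 40, TRUE,
                                prob = c(0.2, 0.8)))))
    res <- hot_sharing_test(lab)
    all_p <<- c(all_p, res$p)
    any(res$significant)
  }, logical(1))
  # stochastically conservative P distribution under independence
  expect_lte(mean(all_p < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / length(all_p)))
  # and family-wise Bonferroni control holds
  expect_lte(mean(family_reject), 0.05)
})
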