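test_that("subtype merging sums constituents and conserves totals", {
  m <- matrix(c(0.2, 0.3, 0.1, 0.4,
                0.05, 0.15, 0.5, 0.3), 2, 4, byrow = TRUE,
              dimnames = list(c("s1", "s2"),
                              c("CD4_naive", "CD4_memory", "CD8_T", "B")))
  # identity map returns the input
  idmap <- data.frame(raw = colnames(m), merged = colnames(m))
  expect_equal(merge_subtypes(m, idmap), m)

  map <- data.frame(raw = c("CD4_naive", "CD4_memory", "CD8_T", "B"),
                    merged = c("CD4_T", "CD4_T", "CD8_T", "B"))
  mm <- merge_subtypes(m, map)
  expect_equal(unname(mm["s1", "CD4_T"]), 0.5)
  # disjoint partition conserves the per-sample total
  expect_equal(rowSums(mm), rowSums(m))

  # the CD4 composite is the sum of its listed constituents
  cd4map <- data.frame(raw = c("CD4_naive", "CD4_memory"),
                       merged = c("CD4_composite", "CD4_composite"))
  expect_equal(unname(merge_subtypes(m, cd4map)[, 1]),
               unname(m[, "CD4_naive"] + m[, "CD4_memory"]))

  expect_error(merge_subtypes(m, data.frame(raw = "nope", merged = "x")),
               "unknown raw label")
})

test_that("phenotype enumeration is cell types x tissues with intersected ids", {
  mk <- function(ids, tissue, ct = c("A", "B")) {
    m <- matrix(stats::runif(length(ids) * length(ct)), length(ids),
                dimnames = list(ids, ct))
    make_score_set(m, tissue)
  }
  ids <- paste0("s", 1:5)
  join <- function(a, b) {
    structure(list(method = a$method,
                   scores = rbind(a$scores, b$scores),
                   tissue = c(a$tissue, b$tissue), scaling_factor = NULL,
                   presence_p = NULL), class = "iqtl_scores")
  }
  r <- join(mk(ids, "t1"), mk(paste0("u", 1:4), "t2"))
  a <- join(mk(ids, "t1"), mk(paste0("u", 1:4), "t2"))
  e <- join(mk(ids[1:4], "t1"), mk(paste0("u", 1:4), "t2"))
  # 2 cell types x 2 tissues + a third tissue only in one method
  ph <- build_phenotypes(r, a, e)
  expect_length(ph, 4)
  # sample s5 present in only two methods is dropped from t1 phenotypes
  expect_setequal(ph[["t1:A"]]$sample_ids, ids[1:4])
  expect_equal(ph[["t2:B"]]$n, 4)
  # 2 x 3 synthetic config gives 6 phenotypes
  r3 <- join(r, mk(paste0("v", 1:3), "t3"))
  a3 <- join(a, mk(paste0("v", 1:3), "t3"))
  e3 <- join(e, mk(paste0("v", 1:3), "t3"))
  expect_length(build_phenotypes(r3, a3, e3), 6)
})

test_that("the five-criterion filter applies strict printed boundaries", {
  good <- function(n) make_phenotype("t", "ct", rel = stats::runif(n, 0.2, 0.4),
                                     abs_ = seq_len(n) / n,
                                     enr = seq_len(n) / n + 0.01,
                                     presence_p = rep(0.01, n))
  crit <- filter_criteria()

  # N = 70 fails, N = 71 passes (strict N > 70)
  expect_length(filter_phenotypes(list(good(70)), crit)$kept, 0)
  expect_length(filter_phenotypes(list(good(71)), crit)$kept, 1)

  # correlation boundary: exactly 0 passes, -0.01 fails
  ph0 <- good(80)
  ph0$scores$enrichment <- rep(c(1, 2), 40)          # engineered cor = 0
  ph0$scores$absolute <- rep(c(1, 1, 2, 2), 20)
  stopifnot(abs(cor(ph0$scores$absolute, ph0$scores$enrichment)) < 1e-12)
  expect_length(filter_phenotypes(list(ph0), crit)$kept, 1)
  phneg <- good(80)
  phneg$scores$enrichment <- rev(phneg$scores$absolute)
  expect_length(filter_phenotypes(list(phneg), crit)$kept, 0)

  # four phenotypes failing one distinct criterion each, audit names them
  p_small <- good(60)
  p_absent <- good(80); p_absent$presence_p[] <- 0.9
  p_sparse <- good(80); p_sparse$scores$relative <- rep(0.01, 80)
  p_line <- good(80); p_line$tissue <- "cellline"
  crit2 <- filter_criteria(excluded_tissues = "cellline")
  res <- filter_phenotypes(list(p_small, p_absent, p_sparse, p_line), crit2)
  expect_length(res$kept, 0)
  expect_equal(res$audit$first_fail[res$audit$phenotype_id == "t:ct"][1],
               "sample_size")
  expect_setequal(unique(res$audit$first_fail),
                  c("sample_size", "presence", "mean_relative", "cell_line"))

  # idempotence and order-independence
  again <- filter_phenotypes(res$kept, crit2)
  expect_length(again$kept, 0)
  keep4 <- list(good(80), good(90))
  expect_equal(length(filter_phenotypes(keep4, crit)$kept),
               length(filter_phenotypes(rev(keep4), crit)$kept))
})

test_that("kept phenotype count is non-increasing in each threshold", {
  set.seed(8)
  phs <- lapply(1:12, function(i)
    make_phenotype("t", paste0("ct", i),
                   rel = stats::runif(90, 0, 0.2),
                   abs_ = stats::runif(90),
                   enr = stats::runif(90, 0, 0.01),
                   presence_p = stats::runif(90)))
  n_loose <- length(filter_phenotypes(phs, filter_criteria(
    n_min = 10, presence_frac = 0.2, mean_rel_min = 0.01,
    mean_enr_min = 1e-4))$kept)
  n_tight <- length(filter_phenotypes(phs, filter_criteria(
    n_min = 10, presence_frac = 0.4, mean_rel_min = 0.05,
    mean_enr_min = 1e-3))$kept)
  expect_lte(n_tight, n_loose)
})

test_that("rank-inverse normal transform maps to the fixed quantile set", {
  x <- c(3.2, -1, 7, 0.5, 2, 9, -4)
  z <- rank_inverse_normal(x)
  n <- length(x)
  expect_equal(sort(z), stats::qnorm((seq_len(n) - 0.5) / n))
  # odd n with distinct values: the median maps to exactly 0
  expect_equal(z[x == stats::median(x)], 0)
  expect_error(rank_inverse_normal(rep(1, 5)), "constant")
})

test_that("ratio phenotypes use the epsilon offset before transforming", {
  num <- c(0, 1, 2, 3)
  den <- c(0, 2, 1, 2)
  r <- (num + 1e-10) / (den + 1e-10)
  expect_equal(r[1], 1)  # 0/0 -> epsilon/epsilon = 1
  z <- ratio_phenotype(num, den)
  expect_true(all(is.finite(z)))
  expect_equal(sort(z), stats::qnorm((1:4 - 0.5) / 4))
  # equal positive vectors give a constant pre-transform ratio: error
  expect_error(ratio_phenotype(c(1, 2, 3), c(1, 2, 3)), "constant")
})

test_that("PC-phenotype regression flags a perfect PC and is calibrated", {
  set.seed(9)
  x <- matrix(stats::rnorm(50 * 40), 50, 40,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:40)))
  pc1 <- stats::prcomp(t(x), center = TRUE, scale. = TRUE)$x[, 1]
  # phenotype equal to PC1 is an exact fit; summary() warns about it
  res <- suppressWarnings(
    pc_phenotype_scan(x, matrix(pc1, dimnames = list(names(pc1), "ph"))))
  expect_lt(res$p[res$pc == "PC1"], 1e-200)
  expect_true(res$significant[res$pc == "PC1"])
  expect_true(all(res$fdr >= res$p))

  ps <- vapply(1:200, function(r) {
    set.seed(100 + r)
    y <- stats::rnorm(40)
    pc_phenotype_scan(x, matrix(y, dimnames = list(colnames(x), "p")),
                      n_pcs = 1)$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_error(pc_phenotype_scan(x[, 1:4], stats::rnorm(4)), "samples")
})
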