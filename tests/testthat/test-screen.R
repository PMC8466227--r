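test_that("spearman rho and p follow the rank-correlation definitions", {
  sp <- spearmanRank(c(1, 2, 3), c(3, 1, 2))
  expect_equal(sp$rho, -0.5)
  expect_equal(sp$rho, bruteSpearman(c(1, 2, 3), c(3, 1, 2)))
  # monotone transform invariance, rho = 1 on any increasing function
  x <- c(0.3, 1.7, 2.2, 5.9, 8.1)
  expect_equal(spearmanRank(x, exp(x))$rho, 1)
  expect_equal(spearmanRank(x, log(x))$rho, 1)
  expect_equal(spearmanRank(x, -3 * x + 2)$rho, -1)
  # agreement with the textbook formula on random tie-free input
  set.seed(21)
  for (i in 1:20) {
    a <- sample(100, 12); b <- sample(100, 12)
    got <- spearmanRank(a, b)
    expect_equal(got$rho, bruteSpearman(a, b))
    # t-approximation p-value recomputed directly
    tv <- got$rho * sqrt(10 / (1 - got$rho^2))
    expect_equal(got$p, 2 * pt(-abs(tv), 10))
  }
  # all-tied input flagged undefined
  expect_false(spearmanRank(rep(1, 6), 1:6)$defined)
})

test_that("spearman is invariant under monotone transforms of either input", {
  set.seed(22)
  x <- runif(40, 0.1, 9); y <- rnorm(40)
  base <- spearmanRank(x, y)$rho
  expect_equal(spearmanRank(log(x), y)$rho, base)
  expect_equal(spearmanRank(x, exp(y))$rho, base)
  expect_equal(spearmanRank(7 * x + 1, 0.1 * y - 4)$rho, base)
})

test_that("FDR adjustment implements the BH step-up rule", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrAdjust(0.37), 0.37)
  expect_equal(fdrAdjust(c(0.5, 1.0)), c(1.0, 1.0))
  expect_error(fdrAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(23)
  for (i in 1:25) {
    p <- runif(sample(2:12, 1))
    adj <- fdrAdjust(p)
    expect_equal(adj, bruteBH(p))
    expect_true(all(adj >= p))
    # order-preserving
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("constant-median normalization equalizes per-sample medians", {
  t1 <- cbind(a = c(2, 10, 18), b = c(4, 20, 36))
  t2 <- cbind(a = c(1, 5, 9), b = c(8, 40, 72))
  rownames(t1) <- rownames(t2) <- paste0("f", 1:3)
  fs <- PMFeatureSet(t1, t2)
  nm <- medianNormalize(fs)
  meds <- c(apply(SummarizedExperiment::assay(nm, "t1"), 2, median),
            apply(SummarizedExperiment::assay(nm, "t2"), 2, median))
  expect_equal(unname(meds), rep(meds[[1]], 4))
  # zeros stay zero; already-equal medians are untouched
  t1z <- cbind(a = c(0, 5, 7), b = c(0, 5, 9))
  fsz <- PMFeatureSet(t1z, t1z)
  nmz <- medianNormalize(fsz)
  expect_equal(SummarizedExperiment::assay(nmz, "t1")[1, ], c(a = 0, b = 0))
  one <- PMFeatureSet(cbind(a = 3, b = 12), cbind(a = 3, b = 12))
  nm1 <- medianNormalize(one)
  v <- SummarizedExperiment::assay(nm1, "t1")
  expect_equal(unname(v[1, "a"]), unname(v[1, "b"]))
})

test_that("the screen flags planted correlates and ranks by |rho|", {
  cfg <- simConfig("morphine", nCases = 122, seed = 31, nNullFeatures = 60,
                   planted = data.frame(feature_id = c("hit", "anti"),
                                        rho = c(0.6, -0.6)))
  co <- simulateCohort(cfg)
  fs <- simulateFeatures(co, cfg)
  scr <- correlationScreen(co, fs, "morphine")
  df <- as.data.frame(scr)
  expect_true(all(c("hit", "anti") %in% df$feature_id[1:4]))
  expect_true(df$significant[df$feature_id == "hit"])
  expect_lt(df$rho[df$feature_id == "anti"], -0.5)
  expect_true(all(diff(abs(df$rho)) <= 1e-12))
  expect_true(all(df$p_fdr >= df$p_raw, na.rm = TRUE))
  # significance rule: |rho| > 0.5 AND adjusted p < 0.05
  expect_equal(df$significant,
               (df$rho > 0.5 | df$rho < -0.5) & df$p_fdr < 0.05)
  # a feature identical to the drug changes correlates perfectly
  recs <- cohortRecords(co, "morphine", validOnly = FALSE)
  recs <- recs[!is.na(recs$pct_change), ]
  m <- matrix(100, 1, nrow(recs), dimnames = list("self", recs$case_id))
  fsSelf <- PMFeatureSet(m, m * (1 + recs$pct_change / 100))
  scrSelf <- correlationScreen(co, fsSelf, "morphine")
  expect_equal(scrSelf$rho[1], 1)
  expect_true(scrSelf$significant[1])
})

test_that("screen output is reproducible and respects topK", {
  cfg <- simConfig("citalopram", nCases = 40, seed = 32, nNullFeatures = 30,
                   planted = data.frame(feature_id = "hit", rho = 0.7))
  co <- simulateCohort(cfg)
  fs <- simulateFeatures(co, cfg)
  s1 <- correlationScreen(co, fs, "citalopram", topK = 5)
  s2 <- correlationScreen(co, fs, "citalopram", topK = 5)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_gte(nrow(s1), min(5L, nrow(s1)))
  expect_true(all(s1$significant | seq_len(nrow(s1)) <= 5))
  p <- withr::local_tempfile(fileext = ".tsv")
  writeScreenTsv(s1, p)
  expect_true(file.exists(p))
  expect_identical(readLines(p)[1],
                   "drug\tfeature_id\trho\tp_fdr\tworkflow_id_level\tsignificant")
})
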