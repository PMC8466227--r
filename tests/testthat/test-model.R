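test_that("80/20 splits use the floor rule and are seed-deterministic", {
  recs <- makeRecords(sprintf("c%03d", 1:137), rep(1, 137), rep(1, 137),
                      rep(-70, 137))
  sp <- trainTestSplit(recs, 0.8, seed = 1)
  expect_equal(nrow(sp$train), 109L)
  expect_equal(nrow(sp$test), 28L)
  expect_equal(nrow(trainTestSplit(recs[1:126, ], 0.8, seed = 1)$train), 100L)
  expect_equal(nrow(trainTestSplit(recs[1:55, ], 0.8, seed = 1)$train), 44L)
  # deterministic and disjoint
  sp2 <- trainTestSplit(recs, 0.8, seed = 1)
  expect_identical(sp$trainIdx, sp2$trainIdx)
  expect_length(intersect(sp$train$case_id, sp$test$case_id), 0)
  expect_error(trainTestSplit(recs[1:4, ], 0.8, seed = 1), "at least 5")
  expect_error(trainTestSplit(recs[1:10, ], 0.05, seed = 1), "degenerate")
})

test_that("a noise-free cohort with a single rate is recovered exactly", {
  set.seed(5)
  recs <- makeLambdaRecords(30, -0.003, sigmaE = 0, lambdaSd = 0)
  fit <- fitLambda(recs)
  expect_equal(fit@lambda, -0.003, tolerance = 1e-8)
})

test_that("with a common sampling interval the fit equals the paired estimator", {
  set.seed(6)
  recs <- makeLambdaRecords(24, -0.004, dtH = rep(70, 24),
                            sigmaE = 0.3, lambdaSd = 0)
  fit <- fitLambda(recs)
  paired <- mean((log(recs$c_t2) - log(recs$c_t1)) / 70)
  expect_equal(fit@lambda, paired, tolerance = 1e-8)
})

test_that("the REML fit matches brute-force likelihood maximization", {
  set.seed(8)
  recs <- makeLambdaRecords(10, -0.0025, sigmaE = 0.25, lambdaSd = 0)
  fit <- fitLambda(recs)
  dat <- data.frame(
    case = factor(rep(recs$case_id, each = 2), levels = recs$case_id),
    y = as.numeric(rbind(log(recs$c_t1), log(recs$c_t2))),
    tau = as.numeric(rbind(rep(0, 10), -recs$delta_t_h)))
  oracle <- bruteForceREML(dat)
  expect_equal(fit@lambda, oracle$lambda, tolerance = 1e-6)
  expect_equal(fit@sigmaResid, oracle$sigma_resid, tolerance = 1e-3)
})

test_that("fitted rates carry the sign of the generating trend", {
  set.seed(9)
  down <- fitLambda(makeLambdaRecords(60, -0.003, sigmaE = 0.25))
  up <- fitLambda(makeLambdaRecords(60, +0.003, sigmaE = 0.25))
  expect_lt(down@lambda, 0)
  expect_gt(up@lambda, 0)
  expect_true(down@ci[1] <= down@lambda && down@lambda <= down@ci[2])
})

test_that("estimation error shrinks with cohort size", {
  set.seed(10)
  err <- function(n, reps = 30) {
    median(vapply(seq_len(reps), function(i) {
      abs(fitLambda(makeLambdaRecords(n, -0.003, sigmaE = 0.25))@lambda + 0.003)
    }, numeric(1)))
  }
  expect_lt(err(300), err(30))
})

test_that("back-calculation evaluates c(t2) * exp(lambda * delta_t)", {
  # 50 * exp(-0.00296044 * -70) evaluated independently
  expect_equal(backCalculate(50, -70, -0.00296044), 50 * exp(0.2072308),
               tolerance = 1e-7)
  expect_equal(backCalculate(3.7, -120, 0), 3.7)
  # algebraic round trip
  c1 <- 2.5; lam <- -0.0031; dt <- 83
  expect_equal(backCalculate(c1 * exp(lam * dt), -dt, lam), c1)
  expect_error(backCalculate(-1, -10, 0.001), "cT2 must be > 0")
  expect_error(backCalculate(Inf, -10, 0.001), "finite")
  expect_warning(backCalculate(1, 10, 0.001), "forward")
})

test_that("prediction accuracy is back-calculated over observed, in percent", {
  recs <- makeRecords("a", 5.0, 5.45 * exp(0.002 * 70), -70)
  acc <- predictionAccuracy(recs, 0.002)
  expect_equal(acc@perCasePct, 109)
  # noise-free test set scores exactly 100% everywhere
  set.seed(12)
  nf <- makeLambdaRecords(10, -0.003, sigmaE = 0, lambdaSd = 0)
  acc2 <- predictionAccuracy(nf, -0.003)
  expect_equal(acc2@perCasePct, rep(100, 10))
  expect_equal(acc2@medianPct, 100)
  expect_error(predictionAccuracy(nf[0, ], -0.003), "empty")
})

test_that("resampling RSD matches the hand-computed definition", {
  lam <- c(-0.0030, -0.0028, -0.0032)
  expect_equal(100 * sd(lam) / abs(mean(lam)), 6.666667, tolerance = 1e-6)
  set.seed(14)
  recs <- makeLambdaRecords(40, -0.003, sigmaE = 0.2)
  rob <- resampleRobustness(recs, nRepeats = 8, seed = 3)
  expect_length(rob@lambdas, 8)
  expect_equal(rob@nConverged, 8L)
  expect_equal(rob@rsdPct,
               100 * sd(rob@lambdas) / abs(mean(rob@lambdas)))
  # reproducible from the master seed
  rob2 <- resampleRobustness(recs, nRepeats = 8, seed = 3)
  expect_identical(rob@lambdas, rob2@lambdas)
})

test_that("bootstrap confidence intervals bracket the point estimate", {
  set.seed(15)
  recs <- makeLambdaRecords(25, -0.003, sigmaE = 0.25)
  fit <- fitLambda(recs, ciMethod = "bootstrap", nBoot = 60, seed = 2)
  expect_true(fit@ci[1] <= fit@lambda && fit@lambda <= fit@ci[2])
  expect_identical(fit@ciMethod, "bootstrap")
})
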