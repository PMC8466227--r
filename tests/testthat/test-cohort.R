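ts <- function(x) as.POSIXct(x, tz = "UTC")

test_that("day-only death estimates are imputed by the noon/midpoint rule", {
  # admission on a later day -> noon of the estimated death day
  expect_equal(
    imputeTimeOfDeath(ts("2020-01-05"), ts("2020-01-06 08:00"), TRUE),
    ts("2020-01-05 12:00"))
  # admission on the same day -> midpoint of midnight and admission
  expect_equal(
    imputeTimeOfDeath(ts("2020-01-05"), ts("2020-01-05 18:00"), TRUE),
    ts("2020-01-05 09:00"))
  # full timestamps pass through unchanged
  expect_equal(
    imputeTimeOfDeath(ts("2020-01-05 03:30"), ts("2020-01-05 10:00"), FALSE),
    ts("2020-01-05 03:30"))
  expect_error(
    imputeTimeOfDeath(ts("2020-01-05"), ts("2020-01-04 23:00"), TRUE),
    "chronology")
})

test_that("imputed time of death is never later than admission", {
  set.seed(41)
  for (i in 1:50) {
    death <- ts("2020-03-01") + floor(runif(1, 0, 5)) * 86400
    adm <- death + runif(1, 60, 5 * 86400)
    out <- imputeTimeOfDeath(death, adm, TRUE)
    expect_lte(as.numeric(out), as.numeric(adm))
    expect_gte(as.numeric(out), as.numeric(death))
  }
})

test_that("sampling intervals are computed in hours with negative delta_t", {
  t0 <- ts("2020-01-01 00:00")
  iv <- computeIntervals(t0, t0 + 9 * 3600, t0 + 79 * 3600)
  expect_equal(iv$pre_admission_h, 9)
  expect_equal(iv$pre_autopsy_h, 79)
  expect_equal(iv$delta_t_h, -70)
  # boundary t0 == t1 is allowed
  iv2 <- computeIntervals(t0, t0, t0 + 3600)
  expect_equal(iv2$pre_admission_h, 0)
  expect_equal(iv2$delta_t_h, -1)
  expect_error(computeIntervals(t0, t0 + 3600, t0 + 3600), "chronology")
})

test_that("intervals are invariant under a common time shift", {
  set.seed(7)
  t0 <- ts("2020-01-01 06:00")
  t1 <- t0 + runif(1, 1, 100) * 3600
  t2 <- t1 + runif(1, 1, 100) * 3600
  base <- computeIntervals(t0, t1, t2)
  for (shiftH in c(-1000, -7.25, 13, 5000)) {
    s <- shiftH * 3600
    shifted <- computeIntervals(t0 + s, t1 + s, t2 + s)
    expect_equal(as.data.frame(shifted), as.data.frame(base))
  }
})

test_that("percentage change follows (c2 - c1)/c1 * 100", {
  expect_equal(percentChange(100, 73), -27)
  expect_equal(percentChange(5, 5), 0)
  expect_equal(percentChange(50, 100), 100)
  expect_error(percentChange(0, 10), "c1 must be > 0")
  expect_error(percentChange(-2, 10), "c1 must be > 0")
})

test_that("percentage change satisfies the reverse-direction identity", {
  set.seed(11)
  c1 <- runif(200, 0.01, 50)
  c2 <- runif(200, 0.01, 50)
  fwd <- percentChange(c1, c2)
  rev <- percentChange(c2, c1)
  expect_equal(fwd, -rev / (1 + rev / 100))
})

test_that("change summaries report median/min/max and 5-95 percentiles", {
  co <- PMCohort(data.frame(
    case_id = paste0("c", 1:3), drug = "diazepam",
    c_t1 = c(100, 100, 100), c_t2 = c(28, 73, 320),
    t0 = "2020-01-01 00:00", t1 = "2020-01-01 09:00",
    t2 = "2020-01-04 07:00", t0_day_only = FALSE))
  s <- summarizeChanges(co, "diazepam")
  expect_equal(s$median_pct, -27)
  expect_equal(s$min_pct, -72)
  expect_equal(s$max_pct, 220)

  # hand-evaluated linear interpolation between order statistics
  co2 <- PMCohort(data.frame(
    case_id = paste0("c", 1:5), drug = "x",
    c_t1 = 100, c_t2 = c(100, 110, 120, 130, 140),
    t0 = "2020-01-01 00:00", t1 = "2020-01-01 09:00",
    t2 = "2020-01-04 07:00", t0_day_only = FALSE))
  s2 <- summarizeChanges(co2, "x")
  expect_equal(s2$median_pct, 20)
  expect_equal(s2$p5_pct, 2)
  expect_equal(s2$p95_pct, 38)
})

test_that("summary ordering invariant holds on random change vectors", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(3:60, 1)
    pct <- rnorm(n, 0, 150)
    co <- PMCohort(data.frame(
      case_id = paste0("c", seq_len(n)), drug = "d",
      c_t1 = 100, c_t2 = pmax(100 + pct, 1e-6),
      t0 = "2020-01-01 00:00", t1 = "2020-01-01 09:00",
      t2 = "2020-01-04 07:00", t0_day_only = FALSE))
    s <- summarizeChanges(co, "d")
    expect_true(s$min_pct <= s$p5_pct && s$p5_pct <= s$median_pct &&
                s$median_pct <= s$p95_pct && s$p95_pct <= s$max_pct)
  }
})

test_that("invalid records are excluded with a reason but retained", {
  expect_message(
    co <- PMCohort(data.frame(
      case_id = c("a", "b", "c"), drug = "d",
      c_t1 = c(10, 0, 10), c_t2 = c(8, 5, 9),
      t0 = "2020-01-01 00:00", t1 = "2020-01-01 09:00",
      t2 = c("2020-01-04 07:00", "2020-01-04 07:00", ""),
      t0_day_only = FALSE)),
    "excluded")
  cs <- caseData(co)
  expect_equal(nrow(cs), 3L)
  expect_equal(cs$model_valid, c(TRUE, FALSE, FALSE))
  expect_match(cs$exclude_reason[2], "concentration")
  expect_match(cs$exclude_reason[3], "timestamp")
  # record c has both concentrations but no t2 time: no percent change
  expect_true(is.na(cs$pct_change[3]))
})

test_that("cohort CSV round-trips through write/read", {
  cfg <- simConfig("diazepam", nCases = 15, seed = 99)
  co <- simulateCohort(cfg)
  p <- withr::local_tempfile(fileext = ".csv")
  writeCohortCsv(co, p)
  co2 <- readCohortCsv(p)
  expect_equal(as.data.frame(caseData(co2)), as.data.frame(caseData(co)))
})
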