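## Seeded synthetic-data generator. Emulates the statistical structure of
## paired two-time-point postmortem cohorts: drug-specific exponential
## time trends with strong inter-individual variability, right-skewed
## sampling-interval distributions, day-only death estimates, lognormal
## measurement noise, heavy-tailed outlier contamination, and endogenous
## features whose percentage changes carry planted Spearman correlations
## with the drug's changes.

## Per-drug generating defaults. lambda_mean values are the published
## fitted rates for the six drugs; lambda_sd (between-case SD of the
## case-specific rate) is not published anywhere and is set to reproduce
## the qualitative spread of the reported percentage-change ranges —
## small for the benzodiazepines, large for the opioids whose changes
## span several orders of magnitude.
.drugProfiles <- data.frame(
  drug = c("diazepam", "nordiazepam", "morphine", "codeine",
           "mirtazapine", "citalopram"),
  lambda_mean = c(-0.00296044, -0.00303677, 0.0014037, 0.00020796,
                  0.00333899, 0.0037752),
  lambda_sd = c(0.004, 0.004, 0.015, 0.013, 0.006, 0.006),
  baseline_logc_mean = c(-1.2, -1.2, -2.0, -2.0, -1.6, -1.4),
  baseline_logc_sd = c(1.0, 1.0, 1.0, 1.0, 1.0, 1.0),
  outlier_fraction = c(0.01, 0.01, 0.04, 0.03, 0.03, 0.03),
  outlier_scale = c(1.0, 1.0, 1.5, 1.5, 1.2, 1.2),
  stringsAsFactors = FALSE)

#' Generating presets for the six study drugs
#'
#' @return data.frame of per-drug generator defaults: published fitted
#'   exponential rates (\code{lambda_mean}, per hour), between-case rate
#'   SDs, baseline log-concentration parameters and outlier settings.
#' @export
drugProfiles <- function() .drugProfiles

#' Build a synthetic-cohort configuration
#'
#' Defaults encode the study conditions: sampling-interval distributions
#' are lognormal (their published means exceed the medians, indicating
#' right skew) with median 9 h pre-admission and 70 h between samplings,
#' log-scale SDs chosen so the distribution means match the published
#' 16 h / 83 h, truncated to the published min-max bounds (pre-admission
#' 1.25-292 h, sampling interval 6.5-434 h, pre-autopsy at most 478 h);
#' 163/477 of cases carry a day-only death estimate; measurement noise
#' is multiplicative lognormal with log-scale SD 0.25; drug-specific
#' rates come from \code{\link{drugProfiles}}.
#'
#' @param drug one of the six preset drug names.
#' @param nCases number of cases.
#' @param lambdaMean,lambdaSd mean and between-case SD of the per-hour
#'   exponential rate (defaults from the drug profile).
#' @param baselineLogcMean,baselineLogcSd natural-log baseline (t1)
#'   concentration distribution.
#' @param sigmaMeas log-scale SD of the multiplicative lognormal
#'   measurement noise applied to both observations.
#' @param preAdmMedianH,preAdmSdLog,preAdmBoundsH pre-admission interval
#'   distribution (lognormal median/log-SD, truncation bounds, hours).
#' @param deltaTMedianH,deltaTSdLog,deltaTBoundsH distribution of the
#'   t1-to-t2 sampling interval magnitude (hours).
#' @param preAutopsyMaxH upper bound on the pre-autopsy interval.
#' @param dayOnlyFraction fraction of cases whose death estimate is
#'   degraded to a calendar date.
#' @param outlierFraction,outlierScale probability and log-Laplace scale
#'   of heavy-tailed contamination of the autopsy concentration.
#' @param nNullFeatures number of independent null features for
#'   \code{\link{simulateFeatures}}.
#' @param planted data.frame with columns \code{feature_id}, \code{rho}:
#'   features planted at target Spearman correlations with the drug's
#'   percentage change.
#' @param seed integer seed; all generator randomness derives from it.
#' @return a \code{\linkS4class{SimConfig}}.
#' @export
simConfig <- function(drug = "diazepam", nCases = 137L,
                      lambdaMean = NULL, lambdaSd = NULL,
                      baselineLogcMean = NULL, baselineLogcSd = NULL,
                      sigmaMeas = 0.25,
                      preAdmMedianH = 9, preAdmSdLog = sqrt(2 * log(16 / 9)),
                      preAdmBoundsH = c(1.25, 292),
                      deltaTMedianH = 70, deltaTSdLog = sqrt(2 * log(83 / 70)),
                      deltaTBoundsH = c(6.5, 434), preAutopsyMaxH = 478,
                      dayOnlyFraction = 163 / 477,
                      outlierFraction = NULL, outlierScale = NULL,
                      nNullFeatures = 200L, planted = NULL, seed = 1L) {
  prof <- .drugProfiles[.drugProfiles$drug == drug, ]
  if (!nrow(prof)) {
    prof <- data.frame(lambda_mean = 0, lambda_sd = 0,
                       baseline_logc_mean = -1.2, baseline_logc_sd = 1,
                       outlier_fraction = 0, outlier_scale = 1)
  }
  pick <- function(x, default) if (is.null(x)) default else x
  planted <- if (is.null(planted))
    DataFrame(feature_id = character(), rho = numeric())
  else DataFrame(feature_id = as.character(planted$feature_id),
                 rho = as.numeric(planted$rho))
  cfg <- new("SimConfig", drug = drug, nCases = as.integer(nCases),
             lambdaMean = pick(lambdaMean, prof$lambda_mean),
             lambdaSd = pick(lambdaSd, prof$lambda_sd),
             baselineLogcMean = pick(baselineLogcMean, prof$baseline_logc_mean),
             baselineLogcSd = pick(baselineLogcSd, prof$baseline_logc_sd),
             sigmaMeas = sigmaMeas,
             preAdmMedianH = preAdmMedianH, preAdmSdLog = preAdmSdLog,
             preAdmBoundsH = preAdmBoundsH,
             deltaTMedianH = deltaTMedianH, deltaTSdLog = deltaTSdLog,
             deltaTBoundsH = deltaTBoundsH, preAutopsyMaxH = preAutopsyMaxH,
             dayOnlyFraction = dayOnlyFraction,
             outlierFraction = pick(outlierFraction, prof$outlier_fraction),
             outlierScale = pick(outlierScale, prof$outlier_scale),
             nNullFeatures = as.integer(nNullFeatures), planted = planted,
             seed = as.integer(seed))
  validObject(cfg)
  cfg
}

## Truncated lognormal draws by rejection.
rtlnorm <- function(n, meanlog, sdlog, bounds) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2L * (n - length(out)) + 10L, meanlog, sdlog)
    out <- c(out, x[x >= bounds[1] & x <= bounds[2]])
  }
  out[seq_len(n)]
}

## Laplace(0, scale) via the difference of two exponentials.
rlaplace <- function(n, scale) scale * (rexp(n) - rexp(n))

#' Simulate a paired two-time-point cohort
#'
#' Per case: draws the pre-admission interval and the t1-to-t2 sampling
#' interval from truncated lognormal distributions (redrawing the latter
#' until the pre-autopsy interval stays within its bound), a
#' case-specific rate \eqn{\lambda_i \sim N(\mu_\lambda,
#' \sigma_\lambda^2)}, and a lognormal baseline concentration; sets the
#' noise-free autopsy concentration to \eqn{c(t_1) e^{\lambda_i (t_2 -
#' t_1)}}; multiplies both observations by independent lognormal
#' measurement noise; with probability \code{outlierFraction} multiplies
#' the autopsy concentration by a heavy-tailed log-Laplace factor
#' (mimicking redistribution spikes without disturbing t1); and degrades
#' the recorded death estimate to a calendar date for the day-only
#' fraction of cases. Deterministic given the config seed.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @return a \code{\linkS4class{PMCohort}}.
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  n <- config@nCases
  anchor <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  if (n == 0L) {
    return(PMCohort(data.frame(case_id = character(), drug = character(),
                               c_t1 = numeric(), c_t2 = numeric(),
                               t0 = character(), t1 = character(),
                               t2 = character(), t0_day_only = logical())))
  }
  withSeed(config@seed, {
    preAdm <- rtlnorm(n, log(config@preAdmMedianH), config@preAdmSdLog,
                      config@preAdmBoundsH)
    dt <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        cand <- rtlnorm(1L, log(config@deltaTMedianH), config@deltaTSdLog,
                        config@deltaTBoundsH)
        if (preAdm[i] + cand <= config@preAutopsyMaxH) { dt[i] <- cand; break }
      }
    }
    ## round intervals to whole seconds so that the intervals recovered
    ## from the written timestamps match the generating ones exactly
    preAdm <- round(preAdm * 3600) / 3600
    dt <- round(dt * 3600) / 3600
    lambdaI <- rnorm(n, config@lambdaMean, config@lambdaSd)
    logC1 <- rnorm(n, config@baselineLogcMean, config@baselineLogcSd)
    c1 <- exp(logC1 + rnorm(n, 0, config@sigmaMeas))
    c2 <- exp(logC1 + lambdaI * dt + rnorm(n, 0, config@sigmaMeas))
    isOut <- runif(n) < config@outlierFraction
    c2[isOut] <- c2[isOut] * exp(rlaplace(sum(isOut), config@outlierScale))
    dayOnly <- runif(n) < config@dayOnlyFraction
    ## stagger true death times across days, with a random clock time
    t0true <- anchor + (seq_len(n) - 1L) * 86400 + floor(runif(n, 0, 86400))
    t1 <- t0true + preAdm * 3600
    t2 <- t1 + dt * 3600
    t0rec <- ifelse(dayOnly, format(t0true, "%Y-%m-%d", tz = "UTC"),
                    format(t0true, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
    suppressMessages(PMCohort(data.frame(
      case_id = sprintf("case%04d", seq_len(n)), drug = config@drug,
      c_t1 = c1, c_t2 = c2, t0 = t0rec,
      t1 = format(t1, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
      t2 = format(t2, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
      t0_day_only = dayOnly)))
  })
}

#' Simulate an endogenous feature table for a cohort
#'
#' Feature percentage changes are generated on the normal-scores scale
#' of the drug's per-case percentage changes. For a feature planted at
#' target Spearman correlation \eqn{\rho}, the latent Gaussian
#' correlation is \eqn{r = 2 \sin(\pi \rho / 6)} (exact for a Gaussian
#' copula) and the feature's latent score is \eqn{z_f = r z_d +
#' \sqrt{1 - r^2}\,\varepsilon}; null features draw independent scores.
#' Latent scores map monotonically to a lognormal change distribution
#' (so Spearman correlations are preserved exactly by construction), and
#' changes are converted to (t1, t2) abundance pairs with lognormal
#' positive baselines. Planted features are labelled targeted/level 1,
#' null features untargeted/level 4. Deterministic given the config
#' seed.
#'
#' @param cohort a \code{\linkS4class{PMCohort}} (the config's drug must
#'   be present).
#' @param config a \code{\linkS4class{SimConfig}}.
#' @return a \code{\linkS4class{PMFeatureSet}} over the cohort's cases
#'   with non-missing percentage changes.
#' @export
simulateFeatures <- function(cohort, config) {
  stopifnot(is(cohort, "PMCohort"), is(config, "SimConfig"))
  recs <- cohortRecords(cohort, config@drug, validOnly = FALSE)
  recs <- recs[!is.na(recs$pct_change), , drop = FALSE]
  n <- nrow(recs)
  if (!n) stop("simulateFeatures: cohort has no usable cases")
  ## Blom normal scores of the drug's percentage changes
  zd <- qnorm((rank(recs$pct_change) - 0.375) / (n + 0.25))
  nNull <- config@nNullFeatures
  planted <- config@planted
  nFeat <- nNull + nrow(planted)
  if (!nFeat) stop("simulateFeatures: no features configured")
  withSeed(config@seed + 1L, {
    zf <- matrix(rnorm(nFeat * n), nFeat, n)
    if (nrow(planted)) {
      r <- 2 * sin(pi * planted$rho / 6)
      for (k in seq_len(nrow(planted)))
        zf[k, ] <- r[k] * zd + sqrt(1 - r[k]^2) * zf[k, ]
    }
    ## monotone map to a lognormal change distribution: median -10%,
    ## log-scale spread 0.5
    pct <- 100 * (exp(-0.105 + 0.5 * zf) - 1)
    base <- matrix(stats::rlnorm(nFeat * n, meanlog = 10, sdlog = 1),
                   nFeat, n)
    t1m <- base
    t2m <- base * (1 + pct / 100)
    ids <- c(if (nrow(planted)) as.character(planted$feature_id),
             sprintf("null%04d", seq_len(nNull)))
    dimnames(t1m) <- dimnames(t2m) <- list(ids, recs$case_id)
    PMFeatureSet(t1m, t2m,
                 workflow = c(rep("targeted", nrow(planted)),
                              rep("untargeted", nNull)),
                 idLevel = c(rep(1L, nrow(planted)), rep(4L, nNull)))
  })
}
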