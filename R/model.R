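## Exponential mixed-effect concentration-change model:
##   c(t1) = c(t2) * exp(lambda * delta_t),  delta_t = t1 - t2 (negative).
## Fitted after natural-log transform as the linear mixed model
##   log c_ij = beta0 + b_i + lambda * tau_ij + eps_ij,
## tau measured in hours since each case's t1 sampling (tau = 0 and
## t2 - t1), with a case-level random intercept b_i. With exactly two
## observations per case a random slope is not separately identifiable
## from the residual, so none is offered.

#' Random train/test split of case records
#'
#' Draws \code{floor(trainFraction * n)} records uniformly without
#' replacement as a training set; the complement is the test set.
#' Deterministic for a given seed. The floor rule reproduces the printed
#' training sizes 137 -> 109, 126 -> 100, 55 -> 44.
#'
#' @param records DataFrame (or data.frame) of case records, one row per
#'   case; needs >= 5 rows.
#' @param trainFraction training proportion in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return list with elements \code{train} and \code{test} (row subsets)
#'   and \code{trainIdx} (the sampled row indices).
#' @export
trainTestSplit <- function(records, trainFraction = 0.8, seed) {
  n <- nrow(records)
  if (is.null(n) || n < 5L)
    stop("trainTestSplit: need at least 5 records")
  if (!(trainFraction > 0 && trainFraction < 1))
    stop("trainTestSplit: trainFraction must be in (0, 1)")
  k <- floor(trainFraction * n)
  if (k < 1L || k >= n)
    stop("trainTestSplit: degenerate split (train size ", k, " of ", n, ")")
  idx <- withSeed(seed, sample.int(n, k))
  list(train = records[idx, , drop = FALSE],
       test = records[-idx, , drop = FALSE],
       trainIdx = sort(idx))
}

## Case-level cluster-robust (sandwich) SE of the slope of the fitted
## random-intercept GLS estimator. Between-case heterogeneity of the
## rate induces residual variance growing with delta_t^2, which the
## model-based SE ignores; the sandwich form is consistent under it.
clusterRobustSE <- function(fit, dat) {
  X <- cbind(1, dat$tau)
  vc <- as.data.frame(VarCorr(fit))
  s2c <- vc$vcov[vc$grp == "case"]
  s2r <- max(vc$vcov[vc$grp == "Residual"], 1e-12)
  beta <- fixef(fit)
  r <- dat$y - X %*% beta
  A <- matrix(0, 2, 2); B <- matrix(0, 2, 2)
  for (idx in split(seq_len(nrow(dat)), dat$case)) {
    Vi <- matrix(s2c, length(idx), length(idx)) + diag(s2r, length(idx))
    Wi <- solve(Vi)
    Xi <- X[idx, , drop = FALSE]
    A <- A + crossprod(Xi, Wi %*% Xi)
    u <- crossprod(Xi, Wi %*% r[idx])
    B <- B + tcrossprod(u)
  }
  Ainv <- solve(A)
  sqrt((Ainv %*% B %*% Ainv)[2, 2])
}

## Long-format model frame: two rows (tau = 0 and t2 - t1) per case.
modelFrame <- function(records) {
  stopifnot(all(records$c_t1 > 0), all(records$c_t2 > 0),
            all(records$delta_t_h < 0))
  n <- nrow(records)
  data.frame(
    case = factor(rep(records$case_id, each = 2L),
                  levels = unique(records$case_id)),
    y = as.numeric(rbind(log(records$c_t1), log(records$c_t2))),
    tau = as.numeric(rbind(rep(0, n), -records$delta_t_h)))
}

#' Fit the exponential concentration-change rate lambda
#'
#' Fits, by REML, the log-scale linear mixed model with fixed slope
#' \code{lambda} (per hour) on time since the admission sampling and a
#' case-level random intercept. A negative lambda means generalized
#' time-dependent concentration decrease. The 2.5-97.5 percent interval
#' is Wald-type by default; a case-resampled percentile bootstrap is
#' available.
#'
#' @param records DataFrame of model-ready case records (e.g. from
#'   \code{\link{cohortRecords}}): columns \code{case_id}, \code{c_t1},
#'   \code{c_t2}, \code{delta_t_h}; needs >= 5 cases with positive
#'   concentrations and \code{delta_t_h < 0}.
#' @param drug drug label stored in the result.
#' @param ciLevel confidence level, default 0.95 (2.5-97.5 percent).
#' @param ciMethod "robust" (default; Wald-type interval with a case-level
#'   cluster-robust sandwich SE, which keeps nominal coverage when the
#'   case-specific rates are heterogeneous), "model" (model-based Wald
#'   SE), or "bootstrap" (percentile, cases resampled with replacement).
#' @param nBoot bootstrap draws when \code{ciMethod = "bootstrap"}.
#' @param seed seed for the bootstrap (ignored otherwise).
#' @return a \code{\linkS4class{ModelFit}}.
#' @export
fitLambda <- function(records, drug = NA_character_, ciLevel = 0.95,
                      ciMethod = c("robust", "model", "bootstrap"),
                      nBoot = 1000L, seed = 1L) {
  ciMethod <- match.arg(ciMethod)
  if (nrow(records) < 5L)
    stop("fitLambda: need at least 5 cases")
  dat <- modelFrame(records)
  msgs <- character()
  fit <- withCallingHandlers(
    lmer(y ~ tau + (1 | case), data = dat, REML = TRUE,
         control = lmerControl(calc.derivs = FALSE,
                               check.conv.singular = "ignore")),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    })
  lambda <- unname(fixef(fit)["tau"])
  se <- if (ciMethod == "robust") clusterRobustSE(fit, dat)
        else sqrt(diag(as.matrix(vcov(fit)))[["tau"]])
  z <- qnorm(1 - (1 - ciLevel) / 2)
  ci <- lambda + c(-1, 1) * z * se
  if (ciMethod == "bootstrap") {
    boots <- withSeed(seed, vapply(seq_len(nBoot), function(b) {
      idx <- sample.int(nrow(records), replace = TRUE)
      rec <- records[idx, , drop = FALSE]
      rec$case_id <- paste0(rec$case_id, ".", seq_along(idx))
      fb <- try(suppressWarnings(suppressMessages(
        lmer(y ~ tau + (1 | case), data = modelFrame(rec), REML = TRUE,
             control = lmerControl(calc.derivs = FALSE,
                                   check.conv.singular = "ignore")))),
        silent = TRUE)
      if (inherits(fb, "try-error")) NA_real_ else unname(fixef(fb)["tau"])
    }, numeric(1)))
    ci <- unname(quantile(boots, c((1 - ciLevel) / 2, 1 - (1 - ciLevel) / 2),
                          na.rm = TRUE, names = FALSE))
  }
  vc <- as.data.frame(VarCorr(fit))
  conv <- !any(grepl("failed to converge|unable to evaluate", msgs))
  new("ModelFit", drug = drug, lambda = lambda,
      ci = sort(c(min(ci[1], lambda), max(ci[2], lambda))),
      ciLevel = ciLevel, ciMethod = ciMethod,
      sigmaCase = vc$sdcor[vc$grp == "case"],
      sigmaResid = vc$sdcor[vc$grp == "Residual"],
      nTrain = nrow(records), converged = conv, messages = msgs)
}

#' @describeIn fitLambda accessor: the fitted per-hour rate.
#' @param object a \code{ModelFit}.
#' @export
lambdaHat <- function(object) object@lambda

#' @describeIn fitLambda accessor: the confidence interval (length 2).
#' @export
lambdaCI <- function(object) object@ci

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit [%s]: lambda = %.8g /h  (%.1f%% CI %.8g .. %.8g, %s)\n",
              ifelse(is.na(object@drug), "?", object@drug), object@lambda,
              100 * object@ciLevel, object@ci[1], object@ci[2],
              object@ciMethod))
  cat(sprintf("  sigma_case = %.4g, sigma_resid = %.4g (log scale), n = %d%s\n",
              object@sigmaCase, object@sigmaResid, object@nTrain,
              if (object@converged) "" else "  [convergence flagged]"))
})

#' Back-calculate a concentration toward the time of death
#'
#' Evaluates \code{c(t2) * exp(lambda * deltaT)}. Under the sign
#' convention \code{deltaT = t1 - t2 <= 0}, this projects the autopsy
#' concentration back to the earlier admission sampling time. The model
#' is blind to the first hours after death, so back-calculation should
#' only target time points at or after each case's admission sampling; a
#' positive \code{deltaT} (forward extrapolation) triggers a warning.
#'
#' @param cT2 concentration at autopsy; must be > 0.
#' @param deltaTH signed time difference t1 - t2 in hours (<= 0).
#' @param lambda per-hour rate.
#' @return back-calculated concentration, vectorized.
#' @examples
#' backCalculate(50, -70, -0.00296044)  # ~61.51
#' @export
backCalculate <- function(cT2, deltaTH, lambda) {
  if (any(!is.finite(cT2)) || any(!is.finite(deltaTH)) || any(!is.finite(lambda)))
    stop("backCalculate: inputs must be finite")
  if (any(cT2 <= 0)) stop("backCalculate: cT2 must be > 0")
  if (any(deltaTH > 0))
    warning("backCalculate: positive deltaT extrapolates forward in time")
  cT2 * exp(lambda * deltaTH)
}

#' Prediction accuracy of back-calculated concentrations on a test set
#'
#' For each test case the autopsy concentration is back-calculated to the
#' admission sampling time with the fitted rate, and accuracy is the
#' back-calculated value divided by the measured t1 concentration, x 100
#' (so 109 percent means a 9 percent overestimate).
#'
#' @param records DataFrame of test-set case records (columns
#'   \code{c_t1}, \code{c_t2}, \code{delta_t_h}).
#' @param lambda per-hour rate (a number or a \code{ModelFit}).
#' @return an \code{\linkS4class{AccuracyResult}}.
#' @export
predictionAccuracy <- function(records, lambda) {
  if (is(lambda, "ModelFit")) lambda <- lambda@lambda
  if (!nrow(records)) stop("predictionAccuracy: empty test set")
  pred <- backCalculate(records$c_t2, records$delta_t_h, lambda)
  acc <- 100 * pred / records$c_t1
  new("AccuracyResult", perCasePct = acc, medianPct = median(acc),
      rangePct = range(acc))
}

setMethod("show", "AccuracyResult", function(object) {
  cat(sprintf("AccuracyResult: median %.1f%%, range %.1f-%.1f%% (n = %d)\n",
              object@medianPct, object@rangePct[1], object@rangePct[2],
              length(object@perCasePct)))
})

#' Robustness of lambda under repeated train/test resampling
#'
#' Repeats the random training-set draw and the model fit
#' \code{nRepeats} times (default 50) and summarizes the spread of the
#' fitted rates as their relative standard deviation,
#' RSD = SD / |mean| x 100. Per-repeat sub-seeds are derived from the
#' master seed by a counter, so results are reproducible. Failed fits
#' are recorded per repeat and skipped in the RSD (count reported), not
#' fatal.
#'
#' @param records DataFrame of model-ready case records for one drug.
#' @param nRepeats number of resampling repeats; default 50.
#' @param trainFraction training proportion; default 0.8.
#' @param seed master seed.
#' @return a \code{\linkS4class{RobustnessResult}}.
#' @export
resampleRobustness <- function(records, nRepeats = 50L, trainFraction = 0.8,
                               seed) {
  nRepeats <- as.integer(nRepeats)
  lambdas <- rep(NA_real_, nRepeats)
  msgs <- character()
  for (i in seq_len(nRepeats)) {
    sp <- trainTestSplit(records, trainFraction, seed = subSeed(seed, i))
    ## only the point estimate is used, so skip the robust-SE work
    f <- try(fitLambda(sp$train, ciMethod = "model"), silent = TRUE)
    if (inherits(f, "try-error")) {
      msgs <- c(msgs, sprintf("repeat %d: %s", i, attr(f, "condition")$message))
    } else lambdas[i] <- f@lambda
  }
  lam <- lambdas[!is.na(lambdas)]
  rsd <- if (length(lam) >= 2L && mean(lam) != 0)
    100 * sd(lam) / abs(mean(lam)) else NA_real_
  if (length(lam) >= 2L && mean(lam) == 0)
    msgs <- c(msgs, "RSD undefined: mean of lambdas is zero")
  new("RobustnessResult", lambdas = lambdas, rsdPct = rsd,
      nRepeats = nRepeats, nConverged = length(lam),
      trainFraction = trainFraction, seed = as.integer(seed),
      messages = msgs)
}

## Per-repeat sub-seed derived from the master seed by a counter,
## kept inside the 32-bit integer range.
subSeed <- function(seed, i) (as.integer(seed) %% 1000000L) * 1000L + i

#' @describeIn resampleRobustness accessor: RSD of lambda in percent.
#' @param object a \code{RobustnessResult}.
#' @export
rsdPct <- function(object) object@rsdPct

setMethod("show", "RobustnessResult", function(object) {
  cat(sprintf(
    "RobustnessResult: %d/%d repeats converged, RSD(lambda) = %.2f%%\n",
    object@nConverged, object@nRepeats, object@rsdPct))
})
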