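## S4 class definitions for the PMR analysis pipeline.

setOldClass("POSIXct")

#' PMCohort: paired two-time-point postmortem cases
#'
#' Container for a cohort of postmortem cases, one record per case x drug,
#' with drug concentrations measured at mortuary admission (t1) and at
#' autopsy (t2), the three timestamps (estimated death t0, admission t1,
#' autopsy t2), derived sampling intervals in hours, and per-case
#' percentage concentration changes. Build it with \code{\link{PMCohort}}
#' or \code{\link{readCohortCsv}}; t0 imputation for day-only death
#' estimates and interval computation happen at construction time.
#'
#' @slot cases a \code{\link[S4Vectors]{DataFrame}} with one row per case x
#'   drug and columns \code{case_id}, \code{drug}, \code{c_t1},
#'   \code{c_t2}, \code{t0}, \code{t1}, \code{t2}, \code{t0_day_only},
#'   derived columns \code{pre_admission_h}, \code{pre_autopsy_h},
#'   \code{delta_t_h}, \code{pct_change}, and bookkeeping columns
#'   \code{model_valid} / \code{exclude_reason}.
#'
#' @aliases PMCohort-class
#' @exportClass PMCohort
setClass("PMCohort", representation(cases = "DataFrame"))

setValidity("PMCohort", function(object) {
  req <- c("case_id", "drug", "c_t1", "c_t2", "t0", "t1", "t2",
           "t0_day_only", "pre_admission_h", "pre_autopsy_h", "delta_t_h",
           "pct_change", "model_valid", "exclude_reason")
  missing <- setdiff(req, colnames(object@cases))
  if (length(missing))
    return(paste("missing cohort columns:", paste(missing, collapse = ", ")))
  cs <- object@cases
  ok <- cs$model_valid
  if (any(ok & (is.na(cs$c_t1) | cs$c_t1 <= 0 | is.na(cs$c_t2) | cs$c_t2 <= 0)))
    return("model-valid records must have positive concentrations at both time points")
  if (any(ok & !(cs$delta_t_h < 0), na.rm = TRUE))
    return("model-valid records must have delta_t_h = t1 - t2 < 0")
  TRUE
})

#' PMFeatureSet: endogenous feature abundances at two postmortem time points
#'
#' A \code{\link[SummarizedExperiment]{SummarizedExperiment}} subclass
#' holding endogenous metabolite feature abundances (normalized peak
#' areas) per case at the two sampling times, as two assays named
#' \code{"t1"} and \code{"t2"} (features x cases). Row metadata carries
#' the acquisition workflow (\code{"targeted"} or \code{"untargeted"})
#' and the metabolomics-standards identification level (1-4) as
#' pass-through annotation.
#'
#' @aliases PMFeatureSet-class
#' @exportClass PMFeatureSet
setClass("PMFeatureSet", contains = "SummarizedExperiment")

setValidity("PMFeatureSet", function(object) {
  an <- assayNames(object)
  if (!all(c("t1", "t2") %in% an))
    return("PMFeatureSet needs assays 't1' and 't2'")
  for (a in c("t1", "t2")) {
    v <- assay(object, a)
    if (any(v < 0, na.rm = TRUE))
      return(sprintf("assay '%s' contains negative abundances", a))
  }
  TRUE
})

#' ModelFit: fitted exponential concentration-change model for one drug
#'
#' Result of \code{\link{fitLambda}}: the per-hour rate \code{lambda}
#' (negative = time-dependent concentration decrease), its 2.5-97.5
#' percent confidence interval, and the variance components of the
#' log-scale linear mixed model (between-case SD of the random intercept
#' and residual SD, both on the natural-log-concentration scale).
#'
#' @slot drug drug name.
#' @slot lambda estimated per-hour rate.
#' @slot ci length-2 numeric, lower and upper confidence bound.
#' @slot ciLevel confidence level (default 0.95).
#' @slot ciMethod "wald" or "bootstrap".
#' @slot sigmaCase between-case SD of the random intercept (log scale).
#' @slot sigmaResid residual SD (log scale).
#' @slot nTrain number of cases used in the fit.
#' @slot converged logical; FALSE when the optimizer reported problems.
#' @slot messages character vector of fit diagnostics.
#'
#' @aliases ModelFit-class
#' @exportClass ModelFit
setClass("ModelFit", representation(
  drug = "character", lambda = "numeric", ci = "numeric",
  ciLevel = "numeric", ciMethod = "character",
  sigmaCase = "numeric", sigmaResid = "numeric",
  nTrain = "integer", converged = "logical", messages = "character"))

setValidity("ModelFit", function(object) {
  if (length(object@ci) != 2L) return("ci must have length 2")
  if (isTRUE(object@converged)) {
    if (!is.na(object@lambda) &&
        !(object@ci[1] <= object@lambda && object@lambda <= object@ci[2]))
      return("lambda must lie inside its confidence interval")
    if (!is.na(object@sigmaCase) && object@sigmaCase < 0)
      return("sigmaCase must be >= 0")
  }
  TRUE
})

#' RobustnessResult: resampled lambda estimates and their RSD
#'
#' Result of \code{\link{resampleRobustness}}: the per-hour rates fitted
#' on repeated random training subsets and their relative standard
#' deviation, the robustness metric (SD / |mean| x 100).
#'
#' @slot lambdas numeric vector, one fitted rate per repeat (NA where a
#'   repeat failed to converge).
#' @slot rsdPct relative standard deviation of the converged lambdas, in
#'   percent; NA (flagged in \code{messages}) if their mean is zero.
#' @slot nRepeats number of repeats requested.
#' @slot nConverged number of repeats that produced a usable fit.
#' @slot trainFraction fraction of cases in each training set.
#' @slot seed master seed.
#' @slot messages diagnostics collected across repeats.
#'
#' @aliases RobustnessResult-class
#' @exportClass RobustnessResult
setClass("RobustnessResult", representation(
  lambdas = "numeric", rsdPct = "numeric", nRepeats = "integer",
  nConverged = "integer", trainFraction = "numeric", seed = "integer",
  messages = "character"))

setValidity("RobustnessResult", function(object) {
  if (length(object@lambdas) != object@nRepeats)
    return("length(lambdas) must equal nRepeats")
  TRUE
})

#' AccuracyResult: back-calculation prediction accuracy on a test set
#'
#' Per-case prediction accuracies (back-calculated t1 concentration
#' divided by the measured t1 concentration, x 100), their median and
#' min-max range.
#'
#' @slot perCasePct per-case accuracies in percent.
#' @slot medianPct median accuracy in percent.
#' @slot rangePct length-2 numeric, min and max accuracy.
#'
#' @aliases AccuracyResult-class
#' @exportClass AccuracyResult
setClass("AccuracyResult", representation(
  perCasePct = "numeric", medianPct = "numeric", rangePct = "numeric"))

#' AgreementResult: Bland-Altman agreement between two methods
#'
#' @slot bias mean difference (input units, or percent in ratio mode).
#' @slot loa length-2 numeric: bias -/+ 1.96 x SD of the differences.
#' @slot perPoint DataFrame of per-pair (mean, difference).
#' @slot n number of pairs.
#' @slot slope OLS slope of difference on mean (proportional bias).
#' @slot slopeP p-value of the proportional-bias test (two-sided t test
#'   on \code{slope}); NA when the means have zero variance or the fit
#'   is exact.
#' @slot mode "absolute" or "ratio".
#'
#' @aliases AgreementResult-class
#' @exportClass AgreementResult
setClass("AgreementResult", representation(
  bias = "numeric", loa = "numeric", perPoint = "DataFrame",
  n = "integer", slope = "numeric", slopeP = "numeric",
  mode = "character"))

#' SimConfig: parameters of the synthetic cohort/feature generator
#'
#' Parameters of the data-generating model: case-specific exponential
#' rates \eqn{\lambda_i \sim N(\mu_\lambda, \sigma_\lambda^2)}, lognormal
#' baseline concentrations, multiplicative lognormal measurement noise,
#' right-skewed (lognormal) sampling-interval distributions truncated to
#' plausibility bounds, a fraction of cases whose death estimate is
#' day-only, heavy-tailed (log-Laplace) outlier contamination of the
#' autopsy concentration, and feature-table structure (null features plus
#' features planted at target Spearman correlations via a Gaussian
#' copula). Build with \code{\link{simConfig}}.
#'
#' @aliases SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig", representation(
  drug = "character", nCases = "integer",
  lambdaMean = "numeric", lambdaSd = "numeric",
  baselineLogcMean = "numeric", baselineLogcSd = "numeric",
  sigmaMeas = "numeric",
  preAdmMedianH = "numeric", preAdmSdLog = "numeric",
  preAdmBoundsH = "numeric",
  deltaTMedianH = "numeric", deltaTSdLog = "numeric",
  deltaTBoundsH = "numeric", preAutopsyMaxH = "numeric",
  dayOnlyFraction = "numeric",
  outlierFraction = "numeric", outlierScale = "numeric",
  nNullFeatures = "integer", planted = "DataFrame",
  seed = "integer"))

setValidity("SimConfig", function(object) {
  bad <- character()
  if (object@nCases < 0L) bad <- c(bad, "nCases must be >= 0")
  if (object@sigmaMeas < 0) bad <- c(bad, "sigmaMeas must be >= 0")
  if (object@lambdaSd < 0) bad <- c(bad, "lambdaSd must be >= 0")
  if (object@dayOnlyFraction < 0 || object@dayOnlyFraction > 1)
    bad <- c(bad, "dayOnlyFraction must be in [0, 1]")
  if (object@outlierFraction < 0 || object@outlierFraction > 1)
    bad <- c(bad, "outlierFraction must be in [0, 1]")
  if (object@preAdmMedianH <= 0 || object@deltaTMedianH <= 0)
    bad <- c(bad, "timing medians must be > 0")
  if (nrow(object@planted) && any(abs(object@planted$rho) >= 1))
    bad <- c(bad, "planted |rho| must be < 1")
  if (length(bad)) paste(bad, collapse = "; ") else TRUE
})
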