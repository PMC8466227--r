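## Bland-Altman agreement between two quantification methods.

#' Bland-Altman method agreement
#'
#' Classic Bland-Altman analysis of paired measurements from two
#' methods: per-pair differences (absolute, or as a percentage of the
#' per-pair mean in ratio mode) plotted against per-pair means, with the
#' bias (mean difference) and the 1.96-SD limits of agreement (SD with
#' the n - 1 denominator). Concentration-dependent (proportional) bias is
#' assessed by an ordinary-least-squares regression of the differences on
#' the means; the two-sided slope p-value is reported.
#'
#' @param a,b numeric vectors of paired measurements (method A, method
#'   B), equal length >= 3; ratio mode requires positive values.
#' @param mode "absolute" (differences a - b) or "ratio"
#'   (100 * (a - b) / pairwise mean).
#' @return an \code{\linkS4class{AgreementResult}}.
#' @examples
#' blandAltman(c(10, 20, 30), c(8, 19, 27))
#' @export
blandAltman <- function(a, b, mode = c("absolute", "ratio")) {
  mode <- match.arg(mode)
  if (length(a) != length(b)) stop("blandAltman: length mismatch")
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 3L) stop("blandAltman: need at least 3 complete pairs")
  m <- (a + b) / 2
  if (mode == "ratio") {
    if (any(a <= 0 | b <= 0))
      stop("blandAltman: ratio mode requires positive values")
    d <- 100 * (a - b) / m
  } else d <- a - b
  bias <- mean(d)
  s <- sd(d)
  slope <- slopeP <- NA_real_
  if (var(m) > 0) {
    fit <- suppressWarnings(lm(d ~ m))
    co <- suppressWarnings(summary(fit))$coefficients
    slope <- co["m", "Estimate"]
    slopeP <- co["m", "Pr(>|t|)"]  # NaN on an exact fit
  } else {
    message("blandAltman: zero variance in pair means; slope test skipped")
  }
  new("AgreementResult", bias = bias,
      loa = bias + c(-1.96, 1.96) * s,
      perPoint = DataFrame(mean = m, difference = d),
      n = n, slope = slope, slopeP = slopeP, mode = mode)
}

setMethod("show", "AgreementResult", function(object) {
  unit <- if (object@mode == "ratio") "%" else ""
  cat(sprintf(
    "AgreementResult (%s): bias %.4g%s, limits of agreement [%.4g, %.4g]%s, n = %d\n",
    object@mode, object@bias, unit, object@loa[1], object@loa[2], unit,
    object@n))
  if (!is.na(object@slopeP))
    cat(sprintf("  proportional-bias slope p = %.3g\n", object@slopeP))
})
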