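## Spearman rank-correlation screen of endogenous feature changes
## against a drug's percentage concentration changes, with FDR control.

#' Spearman rank correlation with a t-approximation p-value
#'
#' Computes rho as the Pearson correlation of mid-ranks (average ranks
#' for ties) and, by default, a p-value from the large-sample
#' approximation t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees
#' of freedom. An exact p-value (tie-free permutation distribution via
#' \code{\link[stats]{cor.test}}) is available for small samples.
#'
#' @param x,y numeric vectors; pairs with an NA in either are dropped.
#' @param pMethod "t" (default) or "exact" (only for n <= 10, no ties).
#' @return list with \code{rho}, \code{p}, \code{n}, and \code{defined}
#'   (FALSE when either rank vector has zero variance, in which case rho
#'   and p are NA).
#' @export
spearmanRank <- function(x, y, pMethod = c("t", "exact")) {
  pMethod <- match.arg(pMethod)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("spearmanRank: need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, defined = FALSE))
  rho <- cor(rx, ry)
  p <- if (pMethod == "exact") {
    if (n > 10L) stop("spearmanRank: exact p only for n <= 10")
    stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
  } else if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, defined = TRUE)
}

#' False-discovery-rate adjustment of p-values
#'
#' Benjamini-Hochberg step-up adjusted p-values (the default), capped at
#' 1 and returned in input order; Benjamini-Yekutieli is available for
#' dependence-robust control.
#'
#' @param p vector of p-values in [0, 1].
#' @param method "BH" (default) or "BY".
#' @return adjusted p-values, same length and order as \code{p}.
#' @export
fdrAdjust <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("fdrAdjust: p-values must lie in [0, 1]")
  p.adjust(p, method = method)
}

#' Screen endogenous features for correlation with drug concentration changes
#'
#' For one drug, computes every feature's per-case percentage change
#' between the two sampling times, correlates it (Spearman) with the
#' drug's per-case percentage concentration change over pairwise-complete
#' cases, adjusts the p-values for multiple testing across all tested
#' features (FDR), and flags as significant the features with
#' |rho| > \code{rhoCut} and FDR-adjusted p < \code{fdrThreshold} (the
#' screen's significance rule: rho greater than 0.5 or smaller than -0.5
#' with FDR-corrected p below 0.05). Feature-case pairs with a
#' non-positive t1 abundance are excluded from the change computation;
#' features with fewer than \code{minPairs} complete pairs, or an
#' undefined correlation (zero rank variance), are skipped and reported.
#'
#' @param cohort a \code{\linkS4class{PMCohort}}.
#' @param features a \code{\linkS4class{PMFeatureSet}}; columns matched
#'   to cohort cases by \code{case_id}.
#' @param drug drug name.
#' @param fdrThreshold significance cut on the adjusted p; default 0.05.
#' @param rhoCut significance cut on |rho|; default 0.5.
#' @param topK if non-NULL, return only the significant features plus the
#'   \code{topK} by |rho|; NULL (default) returns all tested features.
#' @param minPairs minimum pairwise-complete cases per feature; default 5.
#' @param fdrMethod passed to \code{\link{fdrAdjust}}.
#' @return DataFrame sorted by |rho| descending with columns
#'   \code{feature_id}, \code{rho}, \code{p_raw}, \code{p_fdr},
#'   \code{n_pairs}, \code{significant}, \code{workflow},
#'   \code{id_level}; skipped features are listed in
#'   \code{metadata(result)$skipped}.
#' @export
correlationScreen <- function(cohort, features, drug, fdrThreshold = 0.05,
                              rhoCut = 0.5, topK = NULL, minPairs = 5L,
                              fdrMethod = "BH") {
  stopifnot(is(cohort, "PMCohort"), is(features, "PMFeatureSet"))
  recs <- cohortRecords(cohort, drug, validOnly = FALSE)
  recs <- recs[!is.na(recs$pct_change), , drop = FALSE]
  shared <- intersect(recs$case_id, colnames(features))
  if (length(shared) < minPairs)
    stop("correlationScreen: fewer than ", minPairs,
         " cases shared between cohort and feature table")
  drugChange <- setNames(recs$pct_change, recs$case_id)[shared]
  m1 <- assay(features, "t1")[, shared, drop = FALSE]
  m2 <- assay(features, "t2")[, shared, drop = FALSE]
  bad1 <- is.na(m1) | m1 <= 0
  featChange <- (m2 - m1) / m1 * 100
  featChange[bad1] <- NA_real_

  ids <- rownames(features)
  rho <- p <- rep(NA_real_, length(ids))
  np <- integer(length(ids))
  skipped <- character()
  for (i in seq_along(ids)) {
    fc <- featChange[i, ]
    keep <- !is.na(fc) & !is.na(drugChange)
    np[i] <- sum(keep)
    if (np[i] < minPairs) {
      skipped <- c(skipped, sprintf("%s: only %d complete pairs", ids[i], np[i]))
      next
    }
    sp <- spearmanRank(fc[keep], drugChange[keep])
    if (!sp$defined) {
      skipped <- c(skipped, sprintf("%s: undefined correlation (zero rank variance)",
                                    ids[i]))
      next
    }
    rho[i] <- sp$rho; p[i] <- sp$p
  }
  tested <- !is.na(rho)
  pFdr <- rep(NA_real_, length(ids))
  pFdr[tested] <- fdrAdjust(p[tested], method = fdrMethod)
  res <- DataFrame(feature_id = ids, rho = rho, p_raw = p, p_fdr = pFdr,
                   n_pairs = np,
                   significant = tested & abs(rho) > rhoCut & pFdr < fdrThreshold,
                   workflow = rowData(features)$workflow,
                   id_level = rowData(features)$id_level)
  res <- res[tested, , drop = FALSE]
  res <- res[order(-abs(res$rho), res$feature_id), , drop = FALSE]
  if (!is.null(topK)) {
    keep <- res$significant
    keep[seq_len(min(topK, nrow(res)))] <- TRUE
    res <- res[keep, , drop = FALSE]
  }
  S4Vectors::metadata(res)$skipped <- skipped
  S4Vectors::metadata(res)$drug <- drug
  res
}

#' Write a correlation-screen table as TSV
#'
#' One row per reported feature: drug, feature id, rho, FDR-adjusted p,
#' workflow/ID level and the significance flag.
#'
#' @param screen result of \code{\link{correlationScreen}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeScreenTsv <- function(screen, path) {
  df <- data.frame(
    drug = S4Vectors::metadata(screen)$drug,
    feature_id = screen$feature_id,
    rho = sprintf("%.5f", screen$rho),
    p_fdr = sprintf("%.3g", screen$p_fdr),
    workflow_id_level = paste0(screen$workflow, "/", screen$id_level),
    significant = screen$significant)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
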