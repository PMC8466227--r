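## Endogenous feature tables: construction, long-CSV I/O, constant-median
## normalization.

#' Construct a PMFeatureSet from paired abundance matrices
#'
#' @param t1,t2 numeric matrices (features x cases) of abundances at the
#'   admission and autopsy sampling times; equal dimnames required.
#' @param workflow per-feature acquisition workflow ("targeted" or
#'   "untargeted").
#' @param idLevel per-feature metabolomics-standards identification
#'   level (1 confirmed ... 4 unknown); pass-through metadata.
#' @return a \code{\linkS4class{PMFeatureSet}}.
#' @export
PMFeatureSet <- function(t1, t2, workflow = rep("untargeted", nrow(t1)),
                         idLevel = rep(4L, nrow(t1))) {
  stopifnot(identical(dim(t1), dim(t2)))
  se <- SummarizedExperiment(
    assays = list(t1 = t1, t2 = t2),
    rowData = DataFrame(workflow = workflow, id_level = as.integer(idLevel),
                        row.names = rownames(t1)))
  new("PMFeatureSet", se)
}

#' Read / write a feature table in long CSV format
#'
#' Long format: columns \code{case_id, feature_id, timepoint (t1|t2),
#' value, workflow, id_level}; one row per case x feature x time point.
#'
#' @param path file path.
#' @return \code{readFeatureCsv}: a \code{\linkS4class{PMFeatureSet}}.
#' @export
readFeatureCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("case_id", "feature_id", "timepoint", "value")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("readFeatureCsv: missing columns: ", paste(missing, collapse = ", "))
  feats <- unique(df$feature_id); cases <- unique(df$case_id)
  mk <- function(tp) {
    m <- matrix(NA_real_, length(feats), length(cases),
                dimnames = list(feats, cases))
    sub <- df[df$timepoint == tp, ]
    m[cbind(match(sub$feature_id, feats), match(sub$case_id, cases))] <- sub$value
    m
  }
  meta <- df[!duplicated(df$feature_id), , drop = FALSE]
  PMFeatureSet(mk("t1"), mk("t2"),
               workflow = if (is.null(meta$workflow))
                 rep("untargeted", length(feats)) else meta$workflow,
               idLevel = if (is.null(meta$id_level))
                 rep(4L, length(feats)) else meta$id_level)
}

#' @rdname readFeatureCsv
#' @param fs a \code{\linkS4class{PMFeatureSet}}.
#' @return \code{writeFeatureCsv}: the path, invisibly.
#' @export
writeFeatureCsv <- function(fs, path) {
  rows <- lapply(c("t1", "t2"), function(tp) {
    m <- assay(fs, tp)
    data.frame(case_id = rep(colnames(m), each = nrow(m)),
               feature_id = rep(rownames(m), ncol(m)),
               timepoint = tp, value = as.vector(m),
               workflow = rep(rowData(fs)$workflow, ncol(m)),
               id_level = rep(rowData(fs)$id_level, ncol(m)))
  })
  df <- do.call(rbind, rows)
  df <- df[!is.na(df$value), , drop = FALSE]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Constant-median normalization of a feature table
#'
#' Scales every sample (each case x time-point column) so that all
#' samples share the same median feature abundance — the global median of
#' the per-sample medians. Medians are taken over the positive values of
#' a sample; zeros stay zero. Cases in which a sample has no positive
#' value are dropped with a warning.
#'
#' @param fs a \code{\linkS4class{PMFeatureSet}}.
#' @return the normalized \code{PMFeatureSet}.
#' @export
medianNormalize <- function(fs) {
  stopifnot(is(fs, "PMFeatureSet"))
  m1 <- assay(fs, "t1"); m2 <- assay(fs, "t2")
  med <- function(m) apply(m, 2, function(v) {
    v <- v[!is.na(v) & v > 0]
    if (length(v)) median(v) else NA_real_
  })
  med1 <- med(m1); med2 <- med(m2)
  dead <- is.na(med1) | is.na(med2)
  if (any(dead)) {
    warning("medianNormalize: dropping ", sum(dead),
            " case(s) with an all-zero sample: ",
            paste(colnames(m1)[dead], collapse = ", "))
    m1 <- m1[, !dead, drop = FALSE]; m2 <- m2[, !dead, drop = FALSE]
    med1 <- med1[!dead]; med2 <- med2[!dead]
  }
  target <- median(c(med1, med2))
  m1 <- sweep(m1, 2, target / med1, `*`)
  m2 <- sweep(m2, 2, target / med2, `*`)
  PMFeatureSet(m1, m2, workflow = rowData(fs)$workflow,
               idLevel = rowData(fs)$id_level)
}
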