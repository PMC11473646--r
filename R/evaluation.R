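#' @include classifiers.R
NULL

#' Trapezoidal one-vs-rest ROC area
#'
#' Area under the ROC curve built from unique score thresholds in descending
#' order, integrated by trapezoid (ties handled by grouping equal scores, so
#' the result equals the Mann-Whitney statistic with 1/2 credit for ties).
#'
#' @param scores numeric scores (higher = more positive).
#' @param positive logical vector, `TRUE` for positive-class samples.
#' @return AUC in `[0, 1]`, or `NaN` when either class is absent.
#' @export
rocAUC <- function(scores, positive) {
  nPos <- sum(positive); nNeg <- sum(!positive)
  if (nPos == 0L || nNeg == 0L) return(NaN)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; pos <- positive[ord]
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- which(grp != c(grp[-1], -1))  # last index of each tie group
  tpr <- c(0, tp[last] / nPos)
  fpr <- c(0, fp[last] / nNeg)
  sum((tpr[-1] + tpr[-length(tpr)]) * diff(fpr)) / 2
}

#' Per-class confusion counts for hard predictions
#'
#' One-vs-rest TP/FP/TN/FN per class; for every class the four counts sum to
#' the number of samples.
#'
#' @param predicted,actual character vectors of class labels.
#' @param classes class label set.
#' @return matrix `[class, c(TP, FP, TN, FN)]`.
#' @export
confusionCounts <- function(predicted, actual, classes) {
  out <- matrix(0L, length(classes), 4,
                dimnames = list(classes, c("TP", "FP", "TN", "FN")))
  for (cls in classes) {
    pp <- predicted == cls; aa <- actual == cls
    out[cls, ] <- c(sum(pp & aa), sum(pp & !aa), sum(!pp & !aa), sum(!pp & aa))
  }
  out
}

# Sensitivity, specificity, LR+ and LR- from one class's confusion counts.
# Zero denominators yield +Inf; 0/0 yields NaN.
lrMetrics <- function(cc) {
  sens <- cc[["TP"]] / (cc[["TP"]] + cc[["FN"]])
  spec <- cc[["TN"]] / (cc[["TN"]] + cc[["FP"]])
  c(sensitivity = sens, specificity = spec,
    lr_pos = sens / (1 - spec), lr_neg = (1 - sens) / spec)
}

#' Sample bootstrap drug sets from the test split
#'
#' Each drug set holds exactly one uniformly sampled row per test drug; sets
#' are drawn independently (with replacement across sets). Deterministic
#' given the seed.
#'
#' @param be a [BiomarkerExperiment-class] (its test split is used).
#' @param nSets number of drug sets.
#' @param seed integer seed.
#' @return integer matrix `[set, drug]` of column indices into the test
#'   split, with drug names as column names.
#' @export
sampleDrugSets <- function(be, nSets, seed) {
  if (missing(seed)) stop("a seed is required")
  te <- bySplit(be, "test")
  drugs <- unique(drugIds(te))
  rowsByDrug <- lapply(drugs, function(d) which(drugIds(te) == d))
  empty <- drugs[lengths(rowsByDrug) == 0L]
  if (length(empty))
    stop("test drug with no surviving rows: ", paste(empty, collapse = ", "))
  withSeed(deriveSeed(seed, "drug-sets"), {
    m <- vapply(rowsByDrug, function(rows)
      rows[sample.int(length(rows), nSets, replace = TRUE)],
      integer(nSets))
    if (nSets == 1L) m <- matrix(m, nrow = 1L)
    colnames(m) <- drugs
    m
  })
}

#' Metrics of one drug set
#'
#' Predicted label is the arg-max probability. Returns multiclass accuracy
#' and, per class one-vs-rest: AUC (that class's probability as score),
#' sensitivity, specificity, LR+ and LR-. Degeneracies are encoded as
#' `Inf`/`NaN`.
#'
#' @param probs probability matrix `[sample, class]` for the set's rows.
#' @param actual character vector of true labels.
#' @return named numeric vector of per-set metrics.
#' @export
setMetrics <- function(probs, actual) {
  classes <- colnames(probs)
  pred <- classes[max.col(probs, ties.method = "first")]
  cc <- confusionCounts(pred, actual, classes)
  out <- c(accuracy = mean(pred == actual))
  for (cls in classes) {
    m <- lrMetrics(cc[cls, ])
    out[paste0("auc_", cls)] <- rocAUC(probs[, cls], actual == cls)
    out[paste0("lr_pos_", cls)] <- m[["lr_pos"]]
    out[paste0("lr_neg_", cls)] <- m[["lr_neg"]]
  }
  out
}

#' Summarize a metric stream into medians and percentile CIs
#'
#' Median and 2.5/97.5 percentiles (linear interpolation between order
#' statistics) over the defined (non-NaN) values of each metric; infinities
#' participate in the ordering. All-NaN metrics are reported undefined.
#'
#' @param metricMatrix numeric matrix `[set, metric]`.
#' @param nSets,seed run metadata stored in the report.
#' @return an [EvaluationReport-class].
#' @export
summarizeMetrics <- function(metricMatrix, nSets = nrow(metricMatrix),
                             seed = NA_integer_) {
  stopifnot(is.matrix(metricMatrix), nrow(metricMatrix) >= 1L)
  rows <- lapply(colnames(metricMatrix), function(mn) {
    v <- metricMatrix[, mn]
    ok <- !is.na(v)  # catches NaN too
    m <- regmatches(mn, regexec("^(auc|lr_pos|lr_neg)_(.+)$", mn))[[1]]
    metric <- if (length(m)) m[2] else mn
    cls <- if (length(m)) m[3] else ""
    q <- if (any(ok)) linearPercentile(v[ok], c(0.5, 0.025, 0.975)) else
      rep(NA_real_, 3)
    data.frame(metric = metric, class = cls, median = q[1], ci_lo = q[2],
               ci_hi = q[3], n_defined = sum(ok), n_total = length(v))
  })
  new("EvaluationReport", metrics = do.call(rbind, rows),
      nSets = as.integer(nSets), seed = as.integer(seed))
}

#' CiPA-style bootstrap evaluation of a classifier
#'
#' Samples `nSets` drug sets (one row per test drug), computes per-set
#' accuracy, one-vs-rest AUC and likelihood ratios, and summarizes each
#' metric as median and 2.5--97.5 percentile CI.
#'
#' @param classifier a [TdpClassifier-class] or a function mapping a feature
#'   matrix to a probability matrix (rows aligned with its input).
#' @param be a [BiomarkerExperiment-class] holding the test split.
#' @param nSets number of bootstrap drug sets (default 10000).
#' @param seed integer seed.
#' @return an [EvaluationReport-class].
#' @export
evaluateClassifier <- function(classifier, be, nSets = 10000L, seed) {
  if (missing(seed)) stop("a seed is required")
  te <- bySplit(be, "test")
  f <- asPredictor(classifier)
  X <- featureMatrix(te)
  if (is(classifier, "TdpClassifier"))
    X <- X[, classifier@featureNames, drop = FALSE]
  probsAll <- f(X)
  actual <- riskLabels(te)
  sets <- sampleDrugSets(be, nSets, seed)
  metricNames <- names(setMetrics(probsAll[sets[1, ], , drop = FALSE],
                                  actual[sets[1, ]]))
  mm <- matrix(NA_real_, nSets, length(metricNames),
               dimnames = list(NULL, metricNames))
  for (s in seq_len(nSets)) {
    idx <- sets[s, ]
    mm[s, ] <- setMetrics(probsAll[idx, , drop = FALSE], actual[idx])
  }
  summarizeMetrics(mm, nSets = nSets, seed = seed)
}
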