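#' @include torsadex-package.R
NULL

# ---------------------------------------------------------------- HillPosterior

#' MCMC posterior sample set for one drug x channel Hill fit
#'
#' Holds post-burn-in samples of the Hill parameters (IC50 in nM, Hill
#' coefficient h) for a single drug and ion channel, together with chain
#' metadata (seed, burn-in, thinning, acceptance rate).
#'
#' @slot drug character drug identifier.
#' @slot channel one of [tdpChannels].
#' @slot samples data.frame with columns `ic50` (nM) and `h`, one row per
#'   retained posterior draw.
#' @slot chainMeta list with elements `seed`, `burnin`, `thin`,
#'   `acceptanceRate`, and `sigma` (the noise sd used, or NA when sampled).
#' @export
setClass("HillPosterior",
  slots = c(drug = "character", channel = "character",
            samples = "data.frame", chainMeta = "list"))

setValidity("HillPosterior", function(object) {
  msg <- character()
  if (length(object@drug) != 1L) msg <- c(msg, "drug must be length 1")
  if (length(object@channel) != 1L || !object@channel %in% tdpChannels)
    msg <- c(msg, sprintf("channel must be one of %s",
                          paste(tdpChannels, collapse = ", ")))
  s <- object@samples
  if (!all(c("ic50", "h") %in% names(s)))
    msg <- c(msg, "samples must have columns ic50 and h")
  else if (nrow(s) > 0 &&
           !(all(is.finite(s$ic50)) && all(is.finite(s$h)) &&
             all(s$ic50 > 0) && all(s$h > 0)))
    msg <- c(msg, "all samples must have finite positive ic50 and h")
  if (length(msg)) msg else TRUE
})

#' @describeIn HillPosterior-class number of posterior draws
#' @param x,object a `HillPosterior`
#' @export
setMethod("length", "HillPosterior", function(x) nrow(x@samples))

#' Posterior samples of a Hill fit
#' @param object a [HillPosterior-class]
#' @return data.frame with columns `ic50`, `h`.
#' @export
hillSamples <- function(object) {
  stopifnot(is(object, "HillPosterior"))
  object@samples
}

setMethod("show", "HillPosterior", function(object) {
  cat(sprintf("HillPosterior: %s x %s, %d samples\n",
              object@drug, object@channel, nrow(object@samples)))
  cat(sprintf("  median IC50 %.4g nM, median h %.3g, acceptance %.2f\n",
              median(object@samples$ic50), median(object@samples$h),
              object@chainMeta$acceptanceRate))
})

# -------------------------------------------------------------- SimulationTrace

#' Recorded pacing trace of the myocyte model
#'
#' Uniform time grid with membrane voltage, intracellular calcium and the
#' seven named currents for one or more recorded beats.
#'
#' @slot time numeric, ms, strictly increasing uniform grid.
#' @slot Vm numeric, mV.
#' @slot Cai numeric, intracellular calcium (mM).
#' @slot currents numeric matrix, one column per channel of [tdpChannels],
#'   A/F.
#' @slot beatStarts integer indices into the grid marking stimulus onsets.
#' @slot cycleLength numeric, ms.
#' @export
setClass("SimulationTrace",
  slots = c(time = "numeric", Vm = "numeric", Cai = "numeric",
            currents = "matrix", beatStarts = "integer",
            cycleLength = "numeric"))

setValidity("SimulationTrace", function(object) {
  msg <- character()
  n <- length(object@time)
  if (length(object@Vm) != n || length(object@Cai) != n ||
      nrow(object@currents) != n)
    msg <- c(msg, "time, Vm, Cai and currents must have equal length")
  if (n > 1 && any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  if (!all(tdpChannels %in% colnames(object@currents)))
    msg <- c(msg, "currents must have one column per channel")
  if (length(object@beatStarts) > 0 &&
      (min(object@beatStarts) < 1L || max(object@beatStarts) > n))
    msg <- c(msg, "beatStarts out of range")
  if (length(msg)) msg else TRUE
})

#' Number of recorded beats in a trace
#' @param trace a [SimulationTrace-class]
#' @export
nBeats <- function(trace) length(trace@beatStarts)

#' Extract a single beat from a trace
#'
#' @param trace a [SimulationTrace-class]
#' @param i beat index (1-based).
#' @return a `SimulationTrace` holding one beat (one beat start).
#' @export
traceBeat <- function(trace, i) {
  stopifnot(is(trace, "SimulationTrace"), i >= 1L, i <= nBeats(trace))
  from <- trace@beatStarts[i]
  # include the next beat's onset sample so every beat spans a full cycle
  to <- if (i < nBeats(trace)) trace@beatStarts[i + 1L] else length(trace@time)
  new("SimulationTrace",
      time = trace@time[from:to], Vm = trace@Vm[from:to],
      Cai = trace@Cai[from:to],
      currents = trace@currents[from:to, , drop = FALSE],
      beatStarts = 1L, cycleLength = trace@cycleLength)
}

setMethod("show", "SimulationTrace", function(object) {
  cat(sprintf("SimulationTrace: %d beats, CL %g ms, %d points (%g ms span)\n",
              nBeats(object), object@cycleLength, length(object@time),
              diff(range(object@time))))
  cat(sprintf("  Vm range [%.1f, %.1f] mV; Cai range [%.2e, %.2e]\n",
              min(object@Vm), max(object@Vm), min(object@Cai), max(object@Cai)))
})

# ---------------------------------------------------------------- BeatSelection

#' Result of the maximum-repolarization-rate beat selection
#'
#' @slot selected integer index of the selected beat (among recorded beats).
#' @slot rates numeric per-beat maximum repolarization-window dVm/dt (mV/ms).
#' @slot category character per-beat repolarization extent:
#'   `"full"` (>= 90%), `"partial"` (>= 30%, < 90%), `"minimal"` (< 30%).
#' @slot failed logical per-beat depolarization-failure flag.
#' @export
setClass("BeatSelection",
  slots = c(selected = "integer", rates = "numeric",
            category = "character", failed = "logical"))

setValidity("BeatSelection", function(object) {
  msg <- character()
  nb <- length(object@rates)
  if (length(object@category) != nb || length(object@failed) != nb)
    msg <- c(msg, "per-beat vectors must have equal length")
  sel <- object@selected
  if (length(sel) != 1L || sel < 1L || sel > nb)
    msg <- c(msg, "selected index out of range")
  else if (object@failed[sel])
    msg <- c(msg, "selected beat is flagged as failed")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BeatSelection", function(object) {
  cat(sprintf("BeatSelection: beat %d of %d (%s, rate %.4g mV/ms); %d failed\n",
              object@selected, length(object@rates),
              object@category[object@selected], object@rates[object@selected],
              sum(object@failed)))
})

# --------------------------------------------------------- BiomarkerExperiment

#' Biomarker feature table as a SummarizedExperiment
#'
#' Rows are the biomarkers, columns are drug samples. `colData` carries
#' `drug` (identifier), `risk` (one of [tdpRiskLevels]) and `split`
#' (`"train"` or `"test"`).
#'
#' @export
setClass("BiomarkerExperiment", contains = "SummarizedExperiment")

setValidity("BiomarkerExperiment", function(object) {
  msg <- character()
  cd <- colData(object)
  need <- c("drug", "risk", "split")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, "colData must contain drug, risk and split")
  else {
    if (!all(cd$risk %in% tdpRiskLevels))
      msg <- c(msg, "risk labels must be high/intermediate/low")
    if (!all(cd$split %in% c("train", "test")))
      msg <- c(msg, "split must be train or test")
  }
  if (length(assays(object)) < 1L)
    msg <- c(msg, "an assay of biomarker values is required")
  else if (anyNA(assay(object)))
    msg <- c(msg, "biomarker values must not contain NA (drop failed samples upstream)")
  if (length(msg)) msg else TRUE
})

#' Construct a BiomarkerExperiment from a feature matrix and sample metadata
#'
#' @param features numeric matrix, samples in rows, biomarkers in columns
#'   (transposed internally to the assay orientation), or already
#'   biomarkers x samples with `byRow = FALSE`.
#' @param drug,risk,split per-sample metadata vectors.
#' @param byRow logical; `TRUE` (default) when `features` has samples in rows.
#' @return a [BiomarkerExperiment-class]
#' @export
BiomarkerExperiment <- function(features, drug, risk, split, byRow = TRUE) {
  m <- if (byRow) t(features) else features
  se <- SummarizedExperiment(
    assays = list(biomarkers = m),
    colData = S4Vectors::DataFrame(drug = as.character(drug),
                                   risk = as.character(risk),
                                   split = as.character(split)))
  new("BiomarkerExperiment", se)
}

#' Feature matrix of a BiomarkerExperiment (samples x biomarkers)
#' @param be a [BiomarkerExperiment-class]
#' @export
featureMatrix <- function(be) t(assay(be, "biomarkers"))

#' Risk labels, drug identifiers and split tags of the samples
#' @param be a [BiomarkerExperiment-class]
#' @export
riskLabels <- function(be) colData(be)$risk

#' @rdname riskLabels
#' @export
drugIds <- function(be) colData(be)$drug

#' @rdname riskLabels
#' @export
splitTags <- function(be) colData(be)$split

#' Subset a BiomarkerExperiment to one split
#' @param be a [BiomarkerExperiment-class]
#' @param split `"train"` or `"test"`.
#' @export
bySplit <- function(be, split) be[, colData(be)$split == split]

setMethod("show", "BiomarkerExperiment", function(object) {
  cd <- colData(object)
  cat(sprintf("BiomarkerExperiment: %d biomarkers x %d samples\n",
              nrow(object), ncol(object)))
  cat(sprintf("  drugs: %d (%d train / %d test rows); classes: %s\n",
              length(unique(cd$drug)), sum(cd$split == "train"),
              sum(cd$split == "test"),
              paste(names(table(cd$risk)), table(cd$risk),
                    sep = "=", collapse = ", ")))
})

# ---------------------------------------------------------------- TdpClassifier

#' A trained TdP risk classifier
#'
#' Bundles the fitted model of one family with the z-score normalization
#' parameters learned on the training split, the winning hyperparameters and
#' the cross-validation score. Probabilities are obtained with [predictRisk()].
#'
#' @slot family one of `"ann"`, `"xgboost"`, `"rf"`, `"svm"`, `"knn"`,
#'   `"rbfnet"`.
#' @slot params list of hyperparameters used for the final fit.
#' @slot norm list with per-feature `mean` and `sd` (training rows only).
#' @slot fit the fitted model object (family-specific).
#' @slot classes class labels, in fixed order.
#' @slot featureNames biomarker names the model was trained on.
#' @slot cvScore mean cross-validation accuracy of the winning combination
#'   (NA when trained without a grid search).
#' @slot seed integer training seed.
#' @export
setClass("TdpClassifier",
  slots = c(family = "character", params = "list", norm = "list",
            fit = "ANY", classes = "character", featureNames = "character",
            cvScore = "numeric", seed = "integer"))

setValidity("TdpClassifier", function(object) {
  fams <- c("ann", "xgboost", "rf", "svm", "knn", "rbfnet")
  if (!(length(object@family) == 1L && object@family %in% fams))
    return(sprintf("family must be one of %s", paste(fams, collapse = ", ")))
  if (!all(c("mean", "sd") %in% names(object@norm)))
    return("norm must contain mean and sd")
  TRUE
})

setMethod("show", "TdpClassifier", function(object) {
  cat(sprintf("TdpClassifier: family %s, %d features, classes %s\n",
              object@family, length(object@featureNames),
              paste(object@classes, collapse = "/")))
  if (is.finite(object@cvScore))
    cat(sprintf("  CV accuracy %.3f; params: %s\n", object@cvScore,
                paste(names(object@params), unlist(object@params),
                      sep = "=", collapse = ", ")))
})

# -------------------------------------------------------------- ShapExplanation

#' Shapley-value attributions for a set of predictions
#'
#' @slot values numeric array `[row, feature, class]` of attributions.
#' @slot baseValues numeric per-class base value: the mean predicted
#'   probability over the background set.
#' @slot prediction numeric matrix `[row, class]` of model outputs for the
#'   explained rows.
#' @slot mode `"exact"` (full coalition enumeration) or `"sampled"`
#'   (random feature permutations).
#' @slot nPerm number of permutations in sampled mode (NA in exact mode).
#' @slot nBackground number of background rows used.
#' @slot seed integer seed (sampled mode).
#' @export
setClass("ShapExplanation",
  slots = c(values = "array", baseValues = "numeric", prediction = "matrix",
            mode = "character", nPerm = "integer", nBackground = "integer",
            seed = "integer"))

setValidity("ShapExplanation", function(object) {
  if (length(dim(object@values)) != 3L)
    return("values must be a 3-d array [row, feature, class]")
  if (dim(object@values)[3] != length(object@baseValues))
    return("class dimension mismatch between values and baseValues")
  if (!object@mode %in% c("exact", "sampled"))
    return("mode must be exact or sampled")
  TRUE
})

setMethod("show", "ShapExplanation", function(object) {
  d <- dim(object@values)
  cat(sprintf("ShapExplanation (%s): %d rows x %d features x %d classes, background %d\n",
              object@mode, d[1], d[2], d[3], object@nBackground))
})

#' Shapley attribution values
#' @param x a [ShapExplanation-class]
#' @return the `[row, feature, class]` array of attributions.
#' @export
shapValues <- function(x) x@values

# ------------------------------------------------------------ ImportanceRanking

#' Mean-|SHAP| biomarker importance
#'
#' @slot perClass matrix `[feature, class]` of mean absolute attributions.
#' @slot overall named numeric overall importance (sum across classes by
#'   default).
#' @slot ranking character features in descending overall importance; ties
#'   broken by feature-name order.
#' @slot aggregate how per-class importances were combined (`"sum"` or
#'   `"max"`).
#' @export
setClass("ImportanceRanking",
  slots = c(perClass = "matrix", overall = "numeric", ranking = "character",
            aggregate = "character"))

setValidity("ImportanceRanking", function(object) {
  if (any(object@perClass < 0) || any(object@overall < 0))
    return("importances must be non-negative")
  if (!setequal(object@ranking, names(object@overall)))
    return("ranking must be a permutation of the feature set")
  TRUE
})

setMethod("show", "ImportanceRanking", function(object) {
  cat("ImportanceRanking (", object@aggregate, " across classes):\n", sep = "")
  ord <- object@overall[object@ranking]
  for (i in seq_along(ord))
    cat(sprintf("  %2d. %-12s %.4g\n", i, names(ord)[i], ord[i]))
})

# ------------------------------------------------------------- EvaluationReport

#' Bootstrap evaluation report
#'
#' Per-metric median and 2.5--97.5 percentile confidence interval over the
#' bootstrap drug sets, with counts of defined (non-NaN) values.
#'
#' @slot metrics data.frame with columns `metric`, `class`, `median`,
#'   `ci_lo`, `ci_hi`, `n_defined`, `n_total`.
#' @slot nSets number of bootstrap drug sets.
#' @slot seed integer sampling seed.
#' @export
setClass("EvaluationReport",
  slots = c(metrics = "data.frame", nSets = "integer", seed = "integer"))

setValidity("EvaluationReport", function(object) {
  m <- object@metrics
  need <- c("metric", "class", "median", "ci_lo", "ci_hi",
            "n_defined", "n_total")
  if (!all(need %in% names(m)))
    return(sprintf("metrics must have columns %s", paste(need, collapse = ", ")))
  fin <- is.finite(m$median) & is.finite(m$ci_lo) & is.finite(m$ci_hi)
  if (any(fin & (m$ci_lo > m$median | m$median > m$ci_hi)))
    return("finite CI bounds must bracket the median")
  TRUE
})

#' Metric table of an evaluation report
#' @param report an [EvaluationReport-class]
#' @export
reportMetrics <- function(report) report@metrics

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: %d drug sets (seed %d)\n",
              object@nSets, object@seed))
  m <- object@metrics
  lab <- ifelse(m$class == "", m$metric, paste(m$metric, m$class))
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-24s %s\n", lab[i],
                fmtCI(m$median[i], m$ci_lo[i], m$ci_hi[i])))
})

# -------------------------------------------------------------- EliminationTrace

#' Trace of Shapley-guided one-by-one feature elimination
#'
#' @slot steps data.frame with one row per evaluated feature set: `step`,
#'   `n_features`, `dropped` (the feature removed after this step, NA on the
#'   final step), `features` (comma-separated surviving set) and summary
#'   evaluation columns.
#' @slot reports list of [EvaluationReport-class], one per step.
#' @slot rankings list of [ImportanceRanking-class], one per step.
#' @export
setClass("EliminationTrace",
  slots = c(steps = "data.frame", reports = "list", rankings = "list"))

setMethod("show", "EliminationTrace", function(object) {
  cat(sprintf("EliminationTrace: %d steps (%d -> %d features)\n",
              nrow(object@steps), max(object@steps$n_features),
              min(object@steps$n_features)))
  print(object@steps[, c("step", "n_features", "dropped")])
})
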