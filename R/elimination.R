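#' @include shap.R evaluation.R
NULL

# Restrict a BiomarkerExperiment to a feature subset (rows of the assay).
selectFeatures <- function(be, features) {
  stopifnot(all(features %in% rownames(be)))
  be[features, ]
}

#' Shapley-guided one-by-one biomarker elimination
#'
#' Loop: train the family on the current feature set, explain training rows
#' with sampled Shapley values, rank features by overall mean-|SHAP|
#' importance, evaluate on bootstrap drug sets, then drop the lowest-ranked
#' feature; repeat until `floor` features remain. Each step's feature set,
#' dropped feature, importance ranking and evaluation report are recorded.
#'
#' @param be a [BiomarkerExperiment-class] (full feature set as rows).
#' @param spec a [familySpec()].
#' @param params hyperparameters for each step's fit (e.g. a grid-search
#'   winner; the grid is searched once, not per step).
#' @param seed integer pipeline seed.
#' @param floor stop when this many features remain (default 6).
#' @param nSets bootstrap drug sets per step evaluation (default 500).
#' @param nExplain training rows to explain per step, deterministically
#'   subsampled (default 64).
#' @param nPerm Shapley permutations per step (default 16).
#' @param aggregate passed to [importanceFromShap()].
#' @return an [EliminationTrace-class].
#' @export
shapGuidedElimination <- function(be, spec, params = NULL, seed, floor = 6L,
                                  nSets = 500L, nExplain = 64L, nPerm = 16L,
                                  aggregate = "sum") {
  if (missing(seed)) stop("a seed is required")
  features <- rownames(be)
  if (length(features) < floor)
    stop("fewer features than the elimination floor")
  nSteps <- length(features) - floor + 1L
  steps <- vector("list", nSteps)
  reports <- vector("list", nSteps)
  rankings <- vector("list", nSteps)
  for (st in seq_len(nSteps)) {
    cur <- selectFeatures(be, features)
    # seed derives from the feature set, so re-running from any intermediate
    # set reproduces the remaining steps exactly
    stepSeed <- deriveSeed(seed, paste0("elim:", paste(features, collapse = ",")))
    clf <- trainFamily(cur, spec, params = params, seed = stepSeed)
    tr <- bySplit(cur, "train")
    Xtr <- featureMatrix(tr)
    expl <- if (nrow(Xtr) > nExplain)
      withSeed(deriveSeed(stepSeed, "explain-rows"),
               sort(sample.int(nrow(Xtr), nExplain))) else seq_len(nrow(Xtr))
    sh <- shapleyValues(clf, Xtr[expl, , drop = FALSE], Xtr,
                        mode = "sampled", nPerm = nPerm, seed = stepSeed)
    rank <- importanceFromShap(sh, aggregate = aggregate)
    report <- evaluateClassifier(clf, cur, nSets = nSets, seed = stepSeed)
    lowest <- rank@ranking[length(rank@ranking)]
    dropped <- if (st < nSteps) lowest else NA_character_
    med <- reportMetrics(report)
    aucMed <- med$median[med$metric == "auc"]
    steps[[st]] <- data.frame(
      step = st, n_features = length(features),
      dropped = dropped,
      features = paste(features, collapse = ","),
      accuracy_median = med$median[med$metric == "accuracy"],
      auc_min_median = suppressWarnings(min(aucMed, na.rm = TRUE)))
    reports[[st]] <- report
    rankings[[st]] <- rank
    if (st < nSteps) features <- setdiff(features, lowest)
  }
  new("EliminationTrace", steps = do.call(rbind, steps),
      reports = reports, rankings = rankings)
}
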