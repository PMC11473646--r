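#' @include elimination.R synthetic.R hill.R
NULL

#' The packaged 28-drug manifest
#'
#' Drug name, maximal free plasma concentration (Cmax, nM), TdP risk label
#' and train/test allocation for the 28 CiPA drugs: 12 training and 16 test
#' drugs across the three risk classes.
#'
#' @return data.frame with columns `drug`, `cmax_nM`, `risk`, `split`.
#' @export
drugManifest <- function() {
  path <- system.file("extdata", "drug_manifest.csv", package = "torsadex",
                      mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 28L, all(df$cmax_nM > 0),
            all(df$risk %in% tdpRiskLevels),
            sum(df$split == "train") == 12L, sum(df$split == "test") == 16L)
  df
}

knownConfigKeys <- c(
  "seed", "outDir", "stages", "family", "grid", "control", "cvFolds",
  "nSets", "eliminationFloor", "eliminationNSets", "nExplain", "nPerm",
  "concentrationMultiple", "qinwardHalved", "feature", "hill", "featureCsv")

#' Build and validate a pipeline run configuration
#'
#' Unknown keys are rejected. Stage toggles select which of the pipeline
#' stages execute; the feature table either comes from the synthetic
#' generator (`stages$features`), or from `featureCsv`.
#'
#' @param ... configuration entries; see `knownConfigKeys` in the source and
#'   the defaults below.
#' @return a validated `RunConfig` list.
#' @export
runConfig <- function(...) {
  user <- list(...)
  if (length(user) == 1L && is.list(user[[1]]) && is.null(names(user)))
    user <- user[[1]]
  unknown <- setdiff(names(user), knownConfigKeys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- list(
    seed = 1L, outDir = tempfile("torsadex-run-"),
    stages = list(hill = FALSE, features = TRUE, train = TRUE,
                  eliminate = FALSE, evaluate = TRUE),
    family = "xgboost", grid = NULL, control = list(), cvFolds = 5L,
    nSets = 10000L, eliminationFloor = 6L, eliminationNSets = 500L,
    nExplain = 64L, nPerm = 16L,
    concentrationMultiple = 2, qinwardHalved = FALSE,
    feature = list(), hill = list(nSamples = 2000L), featureCsv = NULL)
  cfg[names(user)] <- user
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1L)
  badStage <- setdiff(names(cfg$stages),
                      c("hill", "features", "train", "eliminate", "evaluate"))
  if (length(badStage)) stop("unknown stage(s): ", paste(badStage, collapse = ", "))
  needsFeatures <- isTRUE(cfg$stages$train) || isTRUE(cfg$stages$evaluate) ||
    isTRUE(cfg$stages$eliminate)
  if (needsFeatures && !isTRUE(cfg$stages$features) && is.null(cfg$featureCsv))
    stop("training/evaluation requested but no feature source: enable the ",
         "features stage or provide featureCsv")
  structure(cfg, class = "RunConfig")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return [readRunConfig()]: a validated `RunConfig`;
#'   [writeRunConfig()]: `path`, invisibly.
#' @export
readRunConfig <- function(path) {
  runConfig(yaml::read_yaml(path))
}

#' @rdname readRunConfig
#' @param config a `RunConfig`.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a feature CSV into a BiomarkerExperiment
#'
#' Layout written by [writeFeatureTable()]: `drug,sample_index,risk,split`
#' followed by one column per biomarker.
#' @param path CSV path.
#' @export
readFeatureTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  meta <- c("drug", "sample_index", "risk", "split")
  if (!all(meta %in% names(df)))
    stop("feature CSV must have columns ", paste(meta, collapse = ","))
  X <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  BiomarkerExperiment(X, drug = df$drug, risk = df$risk, split = df$split)
}

#' @rdname readFeatureTable
#' @param be a [BiomarkerExperiment-class].
#' @export
writeFeatureTable <- function(be, path) {
  df <- data.frame(drug = drugIds(be),
                   sample_index = seq_len(ncol(be)),
                   risk = riskLabels(be), split = splitTags(be))
  df <- cbind(df, as.data.frame(featureMatrix(be)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in order -- Hill dose-response fitting,
#' feature-table construction, classifier grid search + training,
#' Shapley-guided elimination, bootstrap evaluation -- writing each stage's
#' artifacts plus a JSON manifest of seeds and stage status into the run
#' directory. Re-running an identical config reproduces identical outputs.
#'
#' @param config a [runConfig()].
#' @return invisible list with the run directory and in-memory stage results.
#' @export
runPipeline <- function(config = runConfig()) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  results <- list()
  seed <- config$seed

  if (isTRUE(config$stages$hill)) {
    hillSeed <- deriveSeed(seed, "hill")
    gen <- genDoseResponse(
      ic50 = config$hill$ic50 %||% 500, h = config$hill$h %||% 1.2,
      conc = config$hill$conc %||% c(30, 100, 300, 1000, 3000, 10000),
      replicates = config$hill$replicates %||% 3L,
      noiseSd = config$hill$noiseSd %||% 0.03, seed = hillSeed)
    post <- fitHillMCMC(gen$records,
                        nSamples = config$hill$nSamples %||% 2000L,
                        seed = hillSeed, sigma = gen$truth$noiseSd)
    writeHillPosteriors(post, file.path(config$outDir, "hill_posterior.csv"))
    results$hill <- post
    manifest$stages$hill <- list(seed = hillSeed,
                                 medianIC50 = median(hillSamples(post)$ic50))
  }

  if (isTRUE(config$stages$features)) {
    featSeed <- deriveSeed(seed, "features")
    spec <- do.call(featureSpec, config$feature)
    gen <- genFeatureTable(spec, seed = featSeed)
    be <- gen$table
    writeFeatureTable(be, file.path(config$outDir, "features.csv"))
    results$table <- be
    manifest$stages$features <- list(seed = featSeed, nSamples = ncol(be))
  } else if (!is.null(config$featureCsv)) {
    results$table <- readFeatureTable(config$featureCsv)
  }

  if (isTRUE(config$stages$train)) {
    trainSeed <- deriveSeed(seed, "train")
    spec <- familySpec(config$family,
                       grid = config$grid %||% defaultGrid(config$family),
                       control = config$control)
    gs <- gridSearchCV(results$table, spec, k = config$cvFolds,
                       seed = trainSeed)
    clf <- trainFamily(results$table, spec, params = gs$best,
                       seed = trainSeed, cvScore = gs$bestScore)
    results$gridSearch <- gs
    results$classifier <- clf
    jsonlite::write_json(
      list(family = config$family, best = gs$best, cvScore = gs$bestScore),
      file.path(config$outDir, "model.json"), auto_unbox = TRUE, digits = NA)
    manifest$stages$train <- list(seed = trainSeed, cvScore = gs$bestScore)
  }

  if (isTRUE(config$stages$eliminate)) {
    elimSeed <- deriveSeed(seed, "eliminate")
    spec <- familySpec(config$family,
                       grid = config$grid %||% defaultGrid(config$family),
                       control = config$control)
    trace <- shapGuidedElimination(
      results$table, spec,
      params = results$gridSearch$best %||% NULL,
      seed = elimSeed, floor = config$eliminationFloor,
      nSets = config$eliminationNSets, nExplain = config$nExplain,
      nPerm = config$nPerm)
    results$elimination <- trace
    write.csv(trace@steps, file.path(config$outDir, "elimination.csv"),
              row.names = FALSE)
    manifest$stages$eliminate <- list(seed = elimSeed,
                                      steps = nrow(trace@steps))
  }

  if (isTRUE(config$stages$evaluate)) {
    evalSeed <- deriveSeed(seed, "evaluate")
    report <- evaluateClassifier(results$classifier, results$table,
                                 nSets = config$nSets, seed = evalSeed)
    results$report <- report
    jsonlite::write_json(reportMetrics(report),
                         file.path(config$outDir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, na = "string")
    manifest$stages$evaluate <- list(seed = evalSeed, nSets = config$nSets)
  }

  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(list(outDir = config$outDir), results))
}

#' Write performance-table-shaped CSV reports from a run directory
#'
#' Produces `report_metrics.csv` (rows = metrics; raw numeric median, CI
#' bounds plus a formatted `median (lo, hi)` column) from the evaluation
#' artifacts, and `report_elimination.csv` (one row per elimination step)
#' when an elimination trace is present.
#'
#' @param runDir directory written by [runPipeline()].
#' @return character vector of files written, invisibly.
#' @export
writeReports <- function(runDir) {
  evalPath <- file.path(runDir, "evaluation.json")
  elimPath <- file.path(runDir, "elimination.csv")
  if (!file.exists(evalPath) && !file.exists(elimPath))
    stop("nothing to report: no evaluation or elimination artifacts in ", runDir)
  written <- character()
  if (file.exists(evalPath)) {
    m <- jsonlite::read_json(evalPath, simplifyVector = TRUE)
    m[c("median", "ci_lo", "ci_hi")] <-
      lapply(m[c("median", "ci_lo", "ci_hi")], as.numeric)
    m$formatted <- mapply(fmtCI, m$median, m$ci_lo, m$ci_hi)
    out <- file.path(runDir, "report_metrics.csv")
    write.csv(m, out, row.names = FALSE)
    written <- c(written, out)
  }
  if (file.exists(elimPath)) {
    e <- read.csv(elimPath, stringsAsFactors = FALSE)
    out <- file.path(runDir, "report_elimination.csv")
    write.csv(e, out, row.names = FALSE)
    written <- c(written, out)
  }
  invisible(written)
}
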