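#' @include AllClasses.R mlp.R
NULL

#' Z-score normalization fitted on the training split
#'
#' Per-feature mean and sd are computed on training rows only and applied to
#' both splits, so test rows never influence the normalization (leakage
#' guard). The parameters are stored for reuse at prediction time.
#'
#' @param be a [BiomarkerExperiment-class].
#' @return list with `table` (normalized `BiomarkerExperiment`) and `params`
#'   (list of per-feature `mean` and `sd`).
#' @export
zscoreFitApply <- function(be) {
  stopifnot(is(be, "BiomarkerExperiment"))
  X <- featureMatrix(be)
  tr <- splitTags(be) == "train"
  if (!any(tr)) stop("no training rows to fit normalization on")
  mu <- colMeans(X[tr, , drop = FALSE])
  sdev <- apply(X[tr, , drop = FALSE], 2, sd)
  zero <- which(sdev <= 0 | !is.finite(sdev))
  if (length(zero))
    stop("zero-variance feature(s): ",
         paste(colnames(X)[zero], collapse = ", "))
  Z <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  out <- be
  SummarizedExperiment::assay(out, "biomarkers") <- t(Z)
  list(table = out, params = list(mean = mu, sd = sdev))
}

applyZscore <- function(X, params) {
  sweep(sweep(X[, names(params$mean), drop = FALSE], 2, params$mean),
        2, params$sd, "/")
}

#' Default hyperparameter grids per classifier family
#'
#' The printed grids of the study: ANN batch size \{32, 64\}, optimizer
#' \{rmsprop, adam\}, neurons per hidden layer 5--9, learning rate
#' \{0.1, 0.01, 0.001\}; XGBoost trees \{50, 100, 150, 200\} x depth
#' \{3, 5, 7, 9\}; RF trees \{100, 150, 200\} x mtry \{log2(p), sqrt(p)\} x
#' depth \{unlimited, 3, 5, 7, 9\}; SVM the single combination C = 1,
#' gamma = "scale", RBF kernel; KNN k \{3, 5, 7, 9\} x metric
#' \{euclidean, manhattan\}; RBF network units \{10, 20, 30\} x gamma
#' \{0.1, 0.5, 1\}.
#'
#' @param family one of `"ann"`, `"xgboost"`, `"rf"`, `"svm"`, `"knn"`,
#'   `"rbfnet"`.
#' @return named list of candidate values (a grid).
#' @export
defaultGrid <- function(family) {
  switch(family,
    ann = list(batchSize = c(32L, 64L), optimizer = c("rmsprop", "adam"),
               neurons = 5:9, lr = c(0.1, 0.01, 0.001)),
    xgboost = list(nrounds = c(50L, 100L, 150L, 200L),
                   max_depth = c(3L, 5L, 7L, 9L)),
    rf = list(num.trees = c(100L, 150L, 200L),
              mtry = c("log2", "sqrt"),
              max.depth = c(0L, 3L, 5L, 7L, 9L)),
    svm = list(cost = 1, gamma = "scale"),
    knn = list(k = c(3L, 5L, 7L, 9L), metric = c("euclidean", "manhattan")),
    rbfnet = list(units = c(10L, 20L, 30L), gamma = c(0.1, 0.5, 1)),
    stop("unknown family: ", family))
}

#' Model-family specification for grid search
#'
#' @param family classifier family name.
#' @param grid hyperparameter grid (name -> candidate values); defaults to
#'   [defaultGrid()].
#' @param control family-specific fixed settings (e.g. `epochs` for the ANN,
#'   default 200).
#' @return a `ModelFamilySpec` list.
#' @export
familySpec <- function(family, grid = defaultGrid(family), control = list()) {
  stopifnot(family %in% c("ann", "xgboost", "rf", "svm", "knn", "rbfnet"))
  if (!length(grid) || any(!lengths(grid)))
    stop("grid must be non-empty")
  structure(list(family = family, grid = grid, control = control),
            class = "ModelFamilySpec")
}

# Stratified k-fold assignment: within each class, samples are shuffled and
# dealt round-robin, so fold class proportions match the split's within one
# sample per class. Deterministic given the RNG state.
stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in levels(y)) {
    idx <- which(y == cls)
    if (length(idx) < k)
      stop(sprintf(
        "class '%s' has %d training rows, fewer than %d folds; use more data or fewer folds",
        cls, length(idx), k))
    fold[idx] <- (sample.int(length(idx)) %% k) + 1L
  }
  fold
}

# Fit one family with given hyperparameters on normalized X (matrix) / y.
fitFamily <- function(family, X, y, params, control, seed) {
  switch(family,
    ann = {
      hidden <- rep(params$neurons %||% 6L, 3L)
      mlpFit(X, y, hidden = hidden,
             optimizer = params$optimizer %||% "adam",
             lr = params$lr %||% 0.001,
             batchSize = params$batchSize %||% 32L,
             epochs = control$epochs %||% 200L, seed = seed)
    },
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
      xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = length(levels(y)),
                      max_depth = params$max_depth %||% 6L,
                      eta = control$eta %||% 0.3,
                      nthread = 1L, seed = seed),
        data = dtrain, nrounds = params$nrounds %||% 100L, verbose = 0)
    },
    rf = {
      p <- ncol(X)
      mtry <- params$mtry %||% "sqrt"
      if (is.character(mtry))
        mtry <- max(1L, floor(switch(mtry, log2 = log2(p), sqrt(p))))
      ranger::ranger(x = X, y = y, probability = TRUE,
                     num.trees = params$num.trees %||% 200L,
                     mtry = mtry,
                     max.depth = params$max.depth %||% 0L,
                     seed = seed, num.threads = 1L)
    },
    svm = {
      gamma <- params$gamma %||% "scale"
      if (identical(gamma, "scale")) gamma <- 1 / (ncol(X) * mean(apply(X, 2, var)))
      withSeed(seed,
        e1071::svm(X, y, kernel = "radial", cost = params$cost %||% 1,
                   gamma = gamma, probability = TRUE))
    },
    knn = knnFit(X, y, k = params$k %||% 5L,
                 metric = params$metric %||% "euclidean"),
    rbfnet = rbfFit(X, y, units = params$units %||% 20L,
                    gamma = params$gamma %||% 0.5, seed = seed),
    stop("unknown family: ", family))
}

predictFamily <- function(family, fit, X, classes) {
  P <- switch(family,
    ann = mlpPredict(fit, X),
    xgboost = {
      pr <- predict(fit, xgboost::xgb.DMatrix(X))
      if (!is.matrix(pr))  # older interfaces return a flat row-major vector
        pr <- matrix(pr, ncol = length(classes), byrow = TRUE)
      colnames(pr) <- classes
      pr
    },
    rf = predict(fit, data = X, num.threads = 1L)$predictions,
    svm = {
      pr <- predict(fit, X, probability = TRUE)
      attr(pr, "probabilities")
    },
    knn = knnPredict(fit, X),
    rbfnet = rbfPredict(fit, X))
  P <- P[, classes, drop = FALSE]
  P / rowSums(P)  # guard against sub-1e-9 drift from the backends
}

#' Exhaustive grid search with stratified k-fold cross-validation
#'
#' Every combination in the spec's grid is scored by mean validation accuracy
#' over stratified `k`-fold cross-validation on the training split of `be`
#' (features z-scored inside each fold's training part). The winning
#' combination is the highest mean accuracy; ties break to the first
#' combination in deterministic grid order.
#'
#' @param be a [BiomarkerExperiment-class].
#' @param spec a [familySpec()].
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return list with `best` (winning hyperparameters), `bestScore`, and
#'   `scores` (data.frame of all combinations with mean CV accuracy).
#' @export
gridSearchCV <- function(be, spec, k = 5L, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(inherits(spec, "ModelFamilySpec"))
  tr <- bySplit(be, "train")
  X <- featureMatrix(tr)
  y <- factor(riskLabels(tr), levels = tdpRiskLevels)
  y <- droplevels(y)
  combos <- expand.grid(spec$grid, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  fold <- withSeed(deriveSeed(seed, "cv-folds"), stratifiedFolds(y, k))
  acc <- matrix(NA_real_, nrow(combos), k)
  for (ci in seq_len(nrow(combos))) {
    params <- as.list(combos[ci, , drop = FALSE])
    for (fi in seq_len(k)) {
      hold <- fold == fi
      mu <- colMeans(X[!hold, , drop = FALSE])
      sdev <- apply(X[!hold, , drop = FALSE], 2, sd)
      if (any(sdev <= 0)) stop("zero-variance feature inside a CV fold")
      Z <- sweep(sweep(X, 2, mu), 2, sdev, "/")
      fit <- fitFamily(spec$family, Z[!hold, , drop = FALSE], y[!hold],
                       params, spec$control,
                       seed = deriveSeed(seed, sprintf("cv-%d-%d", ci, fi)))
      P <- predictFamily(spec$family, fit, Z[hold, , drop = FALSE], levels(y))
      pred <- levels(y)[max.col(P, ties.method = "first")]
      acc[ci, fi] <- mean(pred == as.character(y[hold]))
    }
  }
  scores <- cbind(combos, cv_accuracy = rowMeans(acc))
  best <- which.max(scores$cv_accuracy)  # first index on ties
  list(best = as.list(combos[best, , drop = FALSE]),
       bestScore = scores$cv_accuracy[best], scores = scores)
}

#' Train a classifier family on the full training split
#'
#' Fits the family with the given hyperparameters on all training rows of
#' `be` after z-score normalization ([zscoreFitApply()]), producing a
#' [TdpClassifier-class] that emits 3-class probability vectors.
#'
#' @param be a [BiomarkerExperiment-class].
#' @param spec a [familySpec()].
#' @param params hyperparameters (e.g. the `best` element of
#'   [gridSearchCV()]); defaults to the first grid combination.
#' @param seed integer seed.
#' @param cvScore optional CV score to record.
#' @return a [TdpClassifier-class].
#' @export
trainFamily <- function(be, spec, params = NULL, seed, cvScore = NA_real_) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(inherits(spec, "ModelFamilySpec"))
  if (is.null(params))
    params <- lapply(spec$grid, `[[`, 1L)
  tr <- bySplit(be, "train")
  X <- featureMatrix(tr)
  y <- droplevels(factor(riskLabels(tr), levels = tdpRiskLevels))
  mu <- colMeans(X); sdev <- apply(X, 2, sd)
  if (any(sdev <= 0)) stop("zero-variance feature in training data")
  Z <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  fit <- fitFamily(spec$family, Z, y, params, spec$control,
                   seed = deriveSeed(seed, "final-fit"))
  new("TdpClassifier", family = spec$family, params = params,
      norm = list(mean = mu, sd = sdev), fit = fit,
      classes = levels(y), featureNames = colnames(X),
      cvScore = cvScore, seed = as.integer(seed))
}

#' Predict 3-class TdP risk probabilities
#'
#' @param object a [TdpClassifier-class].
#' @param newdata numeric matrix of raw (un-normalized) biomarker values,
#'   samples in rows; columns must cover the classifier's features.
#' @return matrix `[sample, class]` of probabilities summing to 1.
#' @export
setGeneric("predictRisk", function(object, newdata) standardGeneric("predictRisk"))

#' @rdname predictRisk
#' @export
setMethod("predictRisk", "TdpClassifier", function(object, newdata) {
  stopifnot(is.matrix(newdata))
  Z <- applyZscore(newdata, object@norm)
  predictFamily(object@family, object@fit, Z, object@classes)
})
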