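test_that("z-score normalization derives from the training split only", {
  g <- separableTable(seed = 21, samplesPerDrug = 10L)
  z <- zscoreFitApply(g$table)
  Z <- featureMatrix(z$table)
  tr <- splitTags(z$table) == "train"
  expect_equal(unname(colMeans(Z[tr, ])), rep(0, ncol(Z)), tolerance = 1e-9)
  expect_equal(unname(apply(Z[tr, ], 2, sd)), rep(1, ncol(Z)),
               tolerance = 1e-9)
  # shifting a feature by a constant leaves normalized training values alone
  g2 <- g$table
  m <- assay(g2, "biomarkers")
  m["APD90", ] <- m["APD90", ] + 500
  SummarizedExperiment::assay(g2, "biomarkers") <- m
  z2 <- zscoreFitApply(g2)
  expect_equal(featureMatrix(z2$table)[tr, "APD90"], Z[tr, "APD90"],
               tolerance = 1e-9)
  # leakage guard: mutating test rows does not change the fitted parameters
  g3 <- g$table
  m3 <- assay(g3, "biomarkers")
  m3[, splitTags(g3) == "test"] <- m3[, splitTags(g3) == "test"] * 5 + 1
  SummarizedExperiment::assay(g3, "biomarkers") <- m3
  expect_identical(zscoreFitApply(g3)$params, z$params)
  # zero-variance features are refused by name
  m4 <- assay(g$table, "biomarkers")
  m4["qNet", ] <- 1
  g4 <- g$table
  SummarizedExperiment::assay(g4, "biomarkers") <- m4
  expect_error(zscoreFitApply(g4), "qNet")
})

test_that("grid search is exhaustive, stratified, and deterministic", {
  g <- separableTable(seed = 22, samplesPerDrug = 10L)
  spec <- familySpec("knn", grid = list(k = c(3L, 5L, 7L),
                                        metric = c("euclidean", "manhattan")))
  gs <- gridSearchCV(g$table, spec, k = 5, seed = 10)
  expect_equal(nrow(gs$scores), 3L * 2L)
  gs2 <- gridSearchCV(g$table, spec, k = 5, seed = 10)
  expect_identical(gs$scores, gs2$scores)
  # single-combination grid returns that combination
  spec1 <- familySpec("knn", grid = list(k = 5L, metric = "euclidean"))
  gs1 <- gridSearchCV(g$table, spec1, k = 5, seed = 10)
  expect_equal(gs1$best$k, 5L)
  expect_true(is.finite(gs1$bestScore))
})

test_that("stratified folds balance class proportions within one sample", {
  y <- factor(rep(c("high", "intermediate", "low"), times = c(40, 55, 35)))
  fold <- withSeed(1, stratifiedFolds(y, 5))
  for (cls in levels(y)) {
    counts <- table(fold[y == cls])
    expect_lte(diff(range(counts)), 1)
  }
  expect_error(withSeed(1, stratifiedFolds(factor(rep("high", 3)), 5)),
               "fewer than")
})

test_that("every family trains, emits valid probabilities, and is seeded", {
  g <- separableTable(seed = 23, samplesPerDrug = 10L)
  te <- bySplit(g$table, "test")
  probe <- featureMatrix(te)[1:20, ]
  fams <- list(
    ann = familySpec("ann", grid = list(batchSize = 32L, optimizer = "adam",
                                        neurons = 6L, lr = 0.01),
                     control = list(epochs = 30L)),
    xgboost = familySpec("xgboost", grid = list(nrounds = 50L, max_depth = 3L)),
    rf = familySpec("rf", grid = list(num.trees = 100L, mtry = "sqrt",
                                      max.depth = 0L)),
    svm = familySpec("svm"),
    knn = familySpec("knn", grid = list(k = 5L, metric = "manhattan")),
    rbfnet = familySpec("rbfnet", grid = list(units = 15L, gamma = 0.5)))
  for (fam in names(fams)) {
    clf <- trainFamily(g$table, fams[[fam]], seed = 31)
    P <- predictRisk(clf, probe)
    expect_equal(dim(P), c(20L, 3L))
    expect_true(all(P >= 0))
    expect_equal(unname(rowSums(P)), rep(1, 20), tolerance = 1e-9)
    clf2 <- trainFamily(g$table, fams[[fam]], seed = 31)
    expect_equal(predictRisk(clf2, probe), P, tolerance = 1e-12)
  }
})

test_that("separable data gives near-perfect CV and training accuracy", {
  g <- separableTable(seed = 24, samplesPerDrug = 12L)
  X <- featureMatrix(bySplit(g$table, "train"))
  y <- riskLabels(bySplit(g$table, "train"))
  specs <- list(
    rf = familySpec("rf", grid = list(num.trees = 100L, mtry = "sqrt",
                                      max.depth = 0L)),
    knn = familySpec("knn", grid = list(k = 3L, metric = "euclidean")))
  for (fam in names(specs)) {
    spec <- specs[[fam]]
    gs <- gridSearchCV(g$table, spec, k = 5, seed = 12)
    expect_gte(gs$bestScore, 0.95)
    clf <- trainFamily(g$table, spec, params = gs$best, seed = 12)
    pred <- clf@classes[max.col(predictRisk(clf, X), ties.method = "first")]
    expect_equal(mean(pred == y), 1.0)
  }
})

test_that("test rows never influence training (mutation invariance)", {
  g <- separableTable(seed = 25, samplesPerDrug = 10L)
  spec <- familySpec("xgboost", grid = list(nrounds = 50L, max_depth = 3L))
  clf1 <- trainFamily(g$table, spec, seed = 5)
  mutated <- g$table
  m <- assay(mutated, "biomarkers")
  m[, splitTags(mutated) == "test"] <- 0
  SummarizedExperiment::assay(mutated, "biomarkers") <- m
  clf2 <- trainFamily(mutated, spec, seed = 5)
  probe <- featureMatrix(bySplit(g$table, "train"))[1:10, ]
  expect_equal(predictRisk(clf1, probe), predictRisk(clf2, probe),
               tolerance = 1e-12)
  expect_identical(clf1@norm, clf2@norm)
})
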