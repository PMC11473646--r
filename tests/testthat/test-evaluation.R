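test_that("confusion-derived metrics match hand arithmetic", {
  cc <- c(TP = 3, FP = 2, TN = 10, FN = 1)
  m <- lrMetrics(cc)
  expect_equal(m[["sensitivity"]], 0.75)
  expect_equal(m[["specificity"]], 10 / 12)
  expect_equal(m[["lr_pos"]], 4.5)
  expect_equal(m[["lr_neg"]], 0.3)
  # degenerate conventions
  expect_identical(lrMetrics(c(TP = 2, FP = 2, TN = 0, FN = 0))[["lr_neg"]],
                   NaN)  # (1-1)/0
  expect_identical(lrMetrics(c(TP = 2, FP = 0, TN = 3, FN = 1))[["lr_pos"]],
                   Inf)  # perfect specificity

})

test_that("confusion counts conserve totals per class", {
  withr::local_seed(3)
  classes <- tdpRiskLevels
  actual <- sample(classes, 40, replace = TRUE)
  predicted <- sample(classes, 40, replace = TRUE)
  cc <- confusionCounts(predicted, actual, classes)
  for (cls in classes) {
    expect_equal(sum(cc[cls, ]), 40)
    expect_equal(cc[cls, "TP"] + cc[cls, "FN"], sum(actual == cls))
    expect_equal(cc[cls, "TN"] + cc[cls, "FP"], sum(actual != cls))
  }
})

test_that("trapezoidal ROC AUC equals the Mann-Whitney statistic", {
  withr::local_seed(14)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    scores <- rnorm(n)
    if (i %% 3 == 0) scores <- round(scores, 1)  # force ties
    expect_equal(rocAUC(scores, pos), mannWhitneyAUC(scores, pos),
                 tolerance = 1e-12)
  }
  expect_identical(rocAUC(c(1, 2), c(TRUE, TRUE)), NaN)
})

test_that("per-set metrics combine accuracy, AUC and likelihood ratios", {
  classes <- tdpRiskLevels
  # 16-sample set engineered to the hand confusion for the high class:
  # TP=3, FN=1, FP=2, TN=10, and 13/16 correct overall
  actual <- c(rep("high", 4), rep("intermediate", 7), rep("low", 5))
  pred <- c("high", "high", "high", "intermediate",
            "high", "intermediate", "intermediate", "intermediate",
            "intermediate", "intermediate", "intermediate",
            "high", "low", "low", "low", "low")
  probs <- matrix(0.05, 16, 3, dimnames = list(NULL, classes))
  probs[cbind(seq_len(16), match(pred, classes))] <- 0.9
  probs <- probs / rowSums(probs)
  m <- setMetrics(probs, actual)
  expect_equal(m[["accuracy"]], 13 / 16)
  cc <- confusionCounts(pred, actual, classes)
  expect_equal(unname(cc["high", ]), c(3, 2, 10, 1))
  expect_equal(m[["lr_pos_high"]], 4.5)
  expect_equal(m[["lr_neg_high"]], 0.3)
  # perfect classifier: accuracy 1, LR- 0, AUC 1
  perfect <- matrix(0.05, 16, 3, dimnames = list(NULL, classes))
  perfect[cbind(seq_len(16), match(actual, classes))] <- 0.9
  mp <- setMetrics(perfect / rowSums(perfect), actual)
  expect_equal(mp[["accuracy"]], 1)
  for (cls in classes) {
    expect_equal(mp[[paste0("auc_", cls)]], 1)
    expect_equal(mp[[paste0("lr_neg_", cls)]], 0)
  }
})

test_that("drug sets hold one row per test drug, deterministically", {
  g <- separableTable(seed = 31, samplesPerDrug = 4L)
  sets <- sampleDrugSets(g$table, nSets = 50, seed = 9)
  te <- bySplit(g$table, "test")
  expect_equal(dim(sets), c(50L, 16L))
  for (s in c(1, 25, 50))
    expect_equal(unname(drugIds(te)[sets[s, ]]), colnames(sets))
  sets2 <- sampleDrugSets(g$table, nSets = 50, seed = 9)
  expect_identical(sets, sets2)
  # a drug with exactly one row appears in every set
  drop <- which(drugIds(g$table) == "low_test01")[-1]
  one <- g$table[, -drop]
  sets3 <- sampleDrugSets(one, nSets = 20, seed = 9)
  expect_equal(length(unique(sets3[, "low_test01"])), 1L)
})

test_that("summaries use linear-interpolated percentiles and track NaN counts", {
  mm <- cbind(accuracy = as.numeric(1:100))
  rep <- summarizeMetrics(mm)
  met <- reportMetrics(rep)
  expect_equal(met$median, 50.5)
  expect_equal(met$ci_lo, unname(quantile(1:100, 0.025)))
  # constant stream: median = both CI bounds
  repc <- summarizeMetrics(cbind(auc_high = rep(0.7, 40)))
  metc <- reportMetrics(repc)
  expect_equal(c(metc$median, metc$ci_lo, metc$ci_hi), rep(0.7, 3))
  # 30% NaN: percentiles over the defined 70%, counts reported
  v <- c(rep(NaN, 30), 1:70)
  repn <- summarizeMetrics(cbind(lr_pos_low = v))
  metn <- reportMetrics(repn)
  expect_equal(metn$n_defined, 70L)
  expect_equal(metn$median, 35.5)
  # infinities participate in the ordering
  repi <- summarizeMetrics(cbind(lr_pos_high = c(rep(2, 5), rep(Inf, 95))))
  expect_equal(reportMetrics(repi)$median, Inf)
  expect_equal(reportMetrics(repi)$ci_lo, 2)
})

test_that("an oracle classifier evaluates to perfect medians", {
  g <- separableTable(seed = 32, samplesPerDrug = 4L)
  te <- bySplit(g$table, "test")
  lookup <- setNames(riskLabels(te), rownames(featureMatrix(te)))
  oracle <- function(X) {
    P <- matrix(1e-9, nrow(X), 3, dimnames = list(NULL, tdpRiskLevels))
    P[cbind(seq_len(nrow(X)), match(lookup[rownames(X)], tdpRiskLevels))] <- 1
    P / rowSums(P)
  }
  rep <- evaluateClassifier(oracle, g$table, nSets = 200, seed = 17)
  met <- reportMetrics(rep)
  expect_equal(met$median[met$metric == "accuracy"], 1)
  expect_true(all(met$median[met$metric == "lr_neg"] == 0))
  expect_true(all(met$median[met$metric == "auc"] == 1))
  # determinism of the full evaluation
  rep2 <- evaluateClassifier(oracle, g$table, nSets = 200, seed = 17)
  expect_identical(reportMetrics(rep), reportMetrics(rep2))
})

test_that("class separation monotonically raises median AUC", {
  med <- vapply(c(0.3, 1, 3), function(sep) {
    g <- genFeatureTable(featureSpec(samplesPerDrug = 6L, separation = sep,
                                     noiseScale = 2), seed = 40)
    spec <- familySpec("knn", grid = list(k = 5L, metric = "euclidean"))
    clf <- trainFamily(g$table, spec, seed = 8)
    met <- reportMetrics(evaluateClassifier(clf, g$table, nSets = 150,
                                            seed = 8))
    median(met$median[met$metric == "auc"])
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})
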