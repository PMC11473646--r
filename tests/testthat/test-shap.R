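# Linear "per-class" predictor used in several tests: class probabilities are
# an affine link of the same linear score, so attributions have closed form
# under the marginal-expectation value function.
linearPredictor <- function(w, b = 0) {
  function(X) {
    s <- as.vector(X %*% w) + b
    cbind(c1 = s, c2 = 1 - s, c3 = rep(0, length(s)))
  }
}

test_that("additive predictors have closed-form attributions", {
  f <- linearPredictor(c(2, 3))
  x <- matrix(c(1, 1), 1, dimnames = list(NULL, c("f1", "f2")))
  bg <- matrix(0, 4, 2, dimnames = list(NULL, c("f1", "f2")))
  ex <- shapleyValues(f, x, bg, mode = "exact")
  expect_equal(ex@values[1, , "c1"], c(f1 = 2, f2 = 3), tolerance = 1e-8)
  expect_equal(ex@values[1, , "c2"], c(f1 = -2, f2 = -3), tolerance = 1e-8)
  expect_equal(unname(ex@baseValues["c1"]), 0, tolerance = 1e-12)
  # general background: phi_i = w_i (x_i - mean(background_i))
  bg2 <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("f1", "f2")))
  ex2 <- shapleyValues(f, x, bg2, mode = "exact")
  expect_equal(unname(ex2@values[1, , "c1"]),
               unname(c(2, 3) * (c(1, 1) - colMeans(bg2))), tolerance = 1e-8)
})

test_that("dummy and symmetry axioms hold in exact mode", {
  # f ignores feature 3; features 1 and 2 enter symmetrically
  f <- function(X) {
    s <- X[, 1] + X[, 2] + 0.5 * X[, 1] * X[, 2]
    cbind(a = s, b = -s, c = rep(1, nrow(X)))
  }
  x <- matrix(c(1.3, 1.3, 9), 1)
  bg <- matrix(rep(c(0.2, 0.2, -5), each = 6), 6, 3)
  bg <- bg + cbind(rnorm(6, 0, 0.3), 0, rnorm(6, 0, 2))
  bg[, 2] <- bg[, 1]  # identical background marginals for features 1 and 2
  ex <- shapleyValues(f, x, bg, mode = "exact")
  expect_lt(abs(ex@values[1, 3, "a"]), 1e-9)
  expect_equal(ex@values[1, 1, "a"], ex@values[1, 2, "a"], tolerance = 1e-9)
})

test_that("exact mode matches the brute-force enumeration oracle", {
  withr::local_seed(42)
  for (p in c(3L, 5L)) {
    W <- matrix(rnorm(p * 3), p, 3)
    f <- function(X) {
      # nonlinear multi-output predictor
      S <- tanh(X %*% W)
      (S + 1.5) / rowSums(S + 1.5)
    }
    x <- matrix(rnorm(p), 1)
    bg <- matrix(rnorm(5 * p), 5, p)
    ex <- shapleyValues(f, x, bg, mode = "exact")
    oracle <- bruteShapley(f, x[1, ], bg)
    expect_equal(unname(ex@values[1, , ]), unname(oracle), tolerance = 1e-9)
    # efficiency: attributions + base reproduce the prediction
    expect_equal(colSums(ex@values[1, , ]) + ex@baseValues,
                 f(x)[1, ], tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("sampled mode converges toward exact attributions", {
  withr::local_seed(7)
  p <- 8L
  W <- matrix(rnorm(p * 3), p, 3)
  f <- function(X) {
    S <- exp(0.3 * X %*% W)
    S / rowSums(S)
  }
  x <- matrix(rnorm(p), 1)
  bg <- matrix(rnorm(10 * p), 10, p)
  ex <- shapleyValues(f, x, bg, mode = "exact")
  dev <- function(m) {
    sa <- shapleyValues(f, x, bg, mode = "sampled", nPerm = m, seed = 5)
    mean(abs(sa@values - ex@values))
  }
  expect_lt(dev(1024), dev(64))
  expect_error(shapleyValues(f, matrix(rnorm(16), 1),
                             matrix(rnorm(32), 2), mode = "exact"),
               "sampled")
})

test_that("importance is mean |phi| per class, summed and ranked with ties by name", {
  phi <- array(0, c(2, 3, 2),
               dimnames = list(NULL, c("b", "a", "c"), c("x", "y")))
  phi[, 1, 1] <- c(0.2, -0.2)   # feature b, class x
  phi[, 2, 1] <- c(0.1, 0.1)    # feature a
  phi[, 2, 2] <- c(0.3, 0.1)    # feature a, class y
  ex <- new("ShapExplanation", values = phi, baseValues = c(x = 0.5, y = 0.5),
            prediction = matrix(0, 2, 2), mode = "exact",
            nPerm = NA_integer_, nBackground = 1L, seed = 1L)
  imp <- importanceFromShap(ex)
  expect_equal(imp@perClass["b", "x"], 0.2)
  expect_equal(unname(imp@overall["a"]), 0.1 + 0.2)
  expect_equal(imp@ranking, c("a", "b", "c"))
  # all-zero attributions rank by name order
  ex0 <- ex; ex0@values[] <- 0
  expect_equal(importanceFromShap(ex0)@ranking, c("a", "b", "c"))
  # homogeneity: scaling attributions scales importances
  ex3 <- ex; ex3@values <- phi * 3
  expect_equal(importanceFromShap(ex3)@overall, imp@overall * 3)
})

test_that("importance is invariant to row and feature order", {
  withr::local_seed(9)
  phi <- array(rnorm(4 * 3 * 3), c(4, 3, 3),
               dimnames = list(NULL, c("f1", "f2", "f3"),
                               c("high", "intermediate", "low")))
  mk <- function(v) new("ShapExplanation", values = v,
                        baseValues = c(high = 0.3, intermediate = 0.3,
                                       low = 0.4),
                        prediction = matrix(0, 4, 3), mode = "sampled",
                        nPerm = 8L, nBackground = 2L, seed = 1L)
  imp <- importanceFromShap(mk(phi))
  impRow <- importanceFromShap(mk(phi[c(3, 1, 4, 2), , ]))
  impCol <- importanceFromShap(mk(phi[, c(2, 3, 1), ]))
  expect_equal(imp@overall, impRow@overall)
  expect_equal(imp@overall[impCol@ranking], impCol@overall[impCol@ranking])
  expect_equal(sort(imp@ranking), sort(impCol@ranking))
})

test_that("long-format CSV export round-trips attribution values", {
  phi <- array(seq_len(12) / 10, c(2, 3, 2),
               dimnames = list(c("r1", "r2"), c("f1", "f2", "f3"),
                               c("x", "y")))
  ex <- new("ShapExplanation", values = phi, baseValues = c(x = 0, y = 0),
            prediction = matrix(0, 2, 2), mode = "exact",
            nPerm = NA_integer_, nBackground = 1L, seed = 1L)
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeShapValues(ex, tmp)
  df <- read.csv(tmp)
  expect_equal(nrow(df), 12L)
  expect_equal(df$phi[df$row == "r2" & df$feature == "f2" & df$class == "y"],
               phi["r2", "f2", "y"])
})
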