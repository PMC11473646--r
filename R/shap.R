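#' @include classifiers.R
NULL

# Resolve a predictor argument to a function(matrix) -> probability matrix.
asPredictor <- function(predictor) {
  if (is(predictor, "TdpClassifier"))
    function(X) predictRisk(predictor, X)
  else if (is.function(predictor)) predictor
  else stop("predictor must be a TdpClassifier or a function")
}

# Value function evaluations for a batch of coalitions on one explained row:
# features inside the coalition take the row's values, features outside are
# replaced by each background row's values (interventional marginal
# expectation); the value is the mean prediction over the background.
coalitionValues <- function(f, x, background, masks) {
  B <- nrow(background); p <- ncol(background)
  nS <- nrow(masks)
  big <- background[rep(seq_len(B), times = nS), , drop = FALSE]
  rows <- rep(seq_len(nS), each = B)
  for (j in seq_len(p)) {
    on <- masks[rows, j]
    if (any(on)) big[on, j] <- x[j]
  }
  P <- f(big)
  nc <- ncol(P)
  V <- matrix(NA_real_, nS, nc, dimnames = list(NULL, colnames(P)))
  for (cl in seq_len(nc))
    V[, cl] <- rowsum(P[, cl], rows)[, 1] / B
  V
}

#' Shapley-value attributions for a probability classifier
#'
#' Computes per-class Shapley values of each feature for the explained rows.
#' The coalition value is the interventional marginal expectation over the
#' background set: features in the coalition take the explained row's values,
#' the rest are drawn from each background row, and predictions are averaged.
#' `mode = "exact"` enumerates all `2^p` coalitions with the exact Shapley
#' weights (p <= 14); `mode = "sampled"` averages marginal contributions over
#' `nPerm` random feature permutations.
#'
#' @param predictor a [TdpClassifier-class] or a function mapping a feature
#'   matrix to a probability matrix.
#' @param X numeric matrix of rows to explain (raw feature scale for a
#'   classifier).
#' @param background numeric matrix of background rows (same columns); capped
#'   at `maxBackground` rows by deterministic subsampling.
#' @param mode `"exact"` or `"sampled"`.
#' @param nPerm permutations in sampled mode (default 32).
#' @param seed integer seed (sampled mode and background subsampling).
#' @param maxBackground background cap (default 100).
#' @return a [ShapExplanation-class].
#' @export
shapleyValues <- function(predictor, X, background, mode = c("exact", "sampled"),
                          nPerm = 32L, seed = 1L, maxBackground = 100L) {
  mode <- match.arg(mode)
  f <- asPredictor(predictor)
  stopifnot(is.matrix(X), is.matrix(background),
            ncol(X) == ncol(background), nrow(background) >= 1L)
  p <- ncol(X)
  if (mode == "exact" && p > 14L)
    stop("exact mode enumerates 2^p coalitions; use mode = 'sampled' for > 14 features")
  if (nrow(background) > maxBackground) {
    keep <- withSeed(deriveSeed(seed, "shap-background"),
                     sort(sample.int(nrow(background), maxBackground)))
    background <- background[keep, , drop = FALSE]
  }
  P0 <- f(background)
  base <- colMeans(P0)
  nc <- length(base)
  classes <- colnames(P0)
  pred <- f(X)
  n <- nrow(X)
  phi <- array(0, dim = c(n, p, nc),
               dimnames = list(rownames(X), colnames(X), classes))

  if (mode == "exact") {
    masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))[, p:1, drop = FALSE]
    sizes <- rowSums(masks)
    # Shapley kernel weight for adding feature i to coalition S: |S|!(p-|S|-1)!/p!
    wAdd <- exp(lfactorial(0:(p - 1)) + lfactorial(p - 1 - (0:(p - 1))) -
                lfactorial(p))
    key <- as.integer(masks %*% 2^(seq_len(p) - 1L))
    lookup <- integer(2^p); lookup[key + 1L] <- seq_along(key)
    for (r in seq_len(n)) {
      V <- coalitionValues(f, X[r, ], background, masks)
      for (i in seq_len(p)) {
        without <- which(!masks[, i])
        with_i <- lookup[key[without] + bitwShiftL(1L, i - 1L) + 1L]
        w <- wAdd[sizes[without] + 1L]
        for (cl in seq_len(nc))
          phi[r, i, cl] <- sum(w * (V[with_i, cl] - V[without, cl]))
      }
    }
    nPermOut <- NA_integer_
  } else {
    perms <- withSeed(deriveSeed(seed, "shap-perms"),
                      replicate(nPerm, sample.int(p), simplify = FALSE))
    # prefix masks for all permutations: nPerm * (p + 1) coalitions per row
    masks <- matrix(FALSE, nPerm * (p + 1L), p)
    row0 <- 0L
    for (pe in seq_len(nPerm)) {
      for (step in 0:p) {
        if (step > 0) masks[row0 + step + 1L, perms[[pe]][seq_len(step)]] <- TRUE
      }
      row0 <- row0 + p + 1L
    }
    for (r in seq_len(n)) {
      V <- coalitionValues(f, X[r, ], background, masks)
      row0 <- 0L
      for (pe in seq_len(nPerm)) {
        ord <- perms[[pe]]
        for (step in seq_len(p)) {
          i <- ord[step]
          phi[r, i, ] <- phi[r, i, ] +
            (V[row0 + step + 1L, ] - V[row0 + step, ]) / nPerm
        }
        row0 <- row0 + p + 1L
      }
    }
    nPermOut <- as.integer(nPerm)
  }
  new("ShapExplanation", values = phi, baseValues = base, prediction = pred,
      mode = mode, nPerm = nPermOut, nBackground = nrow(background),
      seed = as.integer(seed))
}

#' Mean-|SHAP| biomarker importance
#'
#' Per class, the importance of a feature is the mean over explained rows of
#' the absolute Shapley value; the overall score combines the per-class means
#' (sum by default, optionally max). Features are ranked by descending
#' overall importance, ties broken by feature-name order.
#'
#' @param explanation a [ShapExplanation-class].
#' @param aggregate `"sum"` (default) or `"max"` across classes.
#' @return an [ImportanceRanking-class].
#' @export
importanceFromShap <- function(explanation, aggregate = c("sum", "max")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is(explanation, "ShapExplanation"))
  v <- explanation@values
  perClass <- apply(abs(v), c(2, 3), mean)
  overall <- if (aggregate == "sum") rowSums(perClass) else
    apply(perClass, 1, max)
  feats <- rownames(perClass)
  ord <- order(-overall, feats)
  new("ImportanceRanking", perClass = perClass, overall = overall,
      ranking = feats[ord], aggregate = aggregate)
}

#' Export attributions as long-format CSV
#'
#' Columns `row,feature,class,phi`.
#' @param explanation a [ShapExplanation-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeShapValues <- function(explanation, path) {
  v <- explanation@values
  d <- dim(v); dn <- dimnames(v)
  df <- expand.grid(row = dn[[1]] %||% seq_len(d[1]),
                    feature = dn[[2]], class = dn[[3]],
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$phi <- as.vector(v)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
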