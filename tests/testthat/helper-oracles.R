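# Independent oracles used by the tests. These are deliberately written as
# naive/brute-force implementations, separate from the package's code paths.

# Brute-force Shapley values by direct enumeration of the defining sum:
# phi_i = sum over S subset of N\{i} of |S|!(N-|S|-1)!/N! [V(S u i) - V(S)],
# with V(S) the mean prediction over background rows whose features in S are
# replaced by x's values. Returns a [feature x class] matrix.
bruteShapley <- function(f, x, background) {
  p <- length(x)
  nc <- ncol(f(background[1, , drop = FALSE]))
  valueOf <- function(S) {
    tot <- 0
    for (b in seq_len(nrow(background))) {
      row <- background[b, ]
      row[S] <- x[S]
      tot <- tot + f(matrix(row, 1))
    }
    tot / nrow(background)
  }
  phi <- matrix(0, p, nc)
  others <- function(i) setdiff(seq_len(p), i)
  for (i in seq_len(p)) {
    for (sz in 0:(p - 1)) {
      w <- factorial(sz) * factorial(p - sz - 1) / factorial(p)
      subsets <- if (sz == 0) list(integer()) else
        asplit(combn(others(i), sz), 2)
      for (S in subsets) {
        S <- as.integer(S)
        phi[i, ] <- phi[i, ] + w * (valueOf(c(S, i)) - valueOf(S))
      }
    }
  }
  phi
}

# Dense grid posterior for the Hill fit: uniform grid in (log IC50, h) with
# the package's priors (log-uniform IC50, uniform h) and the same Gaussian
# likelihood with known sigma. Returns posterior mean and median of IC50.
gridHillPosterior <- function(conc, block, sigma, n = 200,
                              logIc50Range = log(range(conc)) + c(-log(30), log(30)),
                              hRange = c(0.05, 5)) {
  logIc50 <- seq(logIc50Range[1], logIc50Range[2], length.out = n)
  h <- seq(hRange[1], hRange[2], length.out = n)
  logLik <- outer(logIc50, h, Vectorize(function(li, hh) {
    mu <- 1 / (1 + exp(hh * (li - log(conc))))
    sum(dnorm(block, mu, sigma, log = TRUE))
  }))
  w <- exp(logLik - max(logLik))
  w <- w / sum(w)
  margIc50 <- rowSums(w)
  list(meanIC50 = sum(exp(logIc50) * margIc50),
       medianIC50 = exp(logIc50[which(cumsum(margIc50) >= 0.5)[1]]))
}

# Mann-Whitney AUC: U statistic / (n+ * n-), with half credit for ties.
mannWhitneyAUC <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  if (!length(sp) || !length(sn)) return(NaN)
  u <- 0
  for (a in sp) u <- u + sum(a > sn) + 0.5 * sum(a == sn)
  u / (length(sp) * length(sn))
}

allOnes <- function() setNames(rep(1, 7), tdpChannels)

# Small pacing protocol for desk-scale simulator tests.
testProtocol <- function(nPrepace = 2, nDrugBeats = 3, nRecorded = 2)
  pacingProtocol(nPrepace = nPrepace, nDrugBeats = nDrugBeats,
                 nRecorded = nRecorded)

# Cache of one control pacing run shared across simulator tests.
.simCache <- new.env(parent = emptyenv())
controlTrace <- function() {
  if (is.null(.simCache$control))
    .simCache$control <- runPacing(bundledModel(), testProtocol())
  .simCache$control
}

# A quick separable feature table shared by classifier-stage tests.
separableTable <- function(seed = 11, samplesPerDrug = 30L, ...) {
  genFeatureTable(featureSpec(samplesPerDrug = samplesPerDrug,
                              separation = 2, noiseScale = 0.5, ...),
                  seed = seed)
}
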