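#' @include AllClasses.R
NULL

# Minimal multilayer perceptron for 3-class probability output:
# ReLU hidden layers, softmax output, categorical cross-entropy, trained by
# mini-batch Adam or RMSprop. Written in-package because no installed R
# package provides a multi-hidden-layer ReLU/softmax network.

mlpInit <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    # He initialization for ReLU layers
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], 0,
                           sqrt(2 / sizes[l])), sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b, sizes = sizes)
}

mlpForward <- function(net, X) {
  L <- length(net$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    A[[l + 1L]] <- if (l < L) pmax(Z, 0) else Z
  }
  # softmax with row-max shift for stability
  Z <- A[[L + 1L]]
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  P <- E / rowSums(E)
  list(probs = P, acts = A)
}

mlpGrad <- function(net, acts, P, Y) {
  L <- length(net$W)
  n <- nrow(P)
  dW <- vector("list", L); db <- vector("list", L)
  delta <- (P - Y) / n
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(acts[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1L) delta <- (delta %*% t(net$W[[l]])) * (acts[[l]] > 0)
  }
  list(dW = dW, db = db)
}

#' Fit a ReLU/softmax multilayer perceptron
#'
#' @param X numeric matrix (rows = samples), already normalized.
#' @param y factor of class labels.
#' @param hidden integer vector of hidden-layer widths (default `c(6, 6, 6)`).
#' @param optimizer `"adam"` or `"rmsprop"`.
#' @param lr learning rate.
#' @param batchSize mini-batch size.
#' @param epochs training epochs (default 200).
#' @param seed integer seed for initialization and batch shuffling.
#' @return an `mlpFit` list usable with [mlpPredict()].
#' @keywords internal
mlpFit <- function(X, y, hidden = c(6, 6, 6), optimizer = "adam", lr = 0.001,
                   batchSize = 32L, epochs = 200L, seed = 1L) {
  stopifnot(is.matrix(X), is.factor(y), nrow(X) == length(y))
  classes <- levels(y)
  Y <- matrix(0, nrow(X), length(classes))
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  withSeed(seed, {
    net <- mlpInit(c(ncol(X), hidden, length(classes)))
    L <- length(net$W)
    mW <- lapply(net$W, function(w) w * 0); mB <- lapply(net$b, function(b) b * 0)
    vW <- mW; vB <- mB
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0L
    n <- nrow(X)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batchSize)) {
        idx <- ord[start:min(start + batchSize - 1L, n)]
        fw <- mlpForward(net, X[idx, , drop = FALSE])
        gr <- mlpGrad(net, fw$acts, fw$probs, Y[idx, , drop = FALSE])
        step <- step + 1L
        for (l in seq_len(L)) {
          if (optimizer == "adam") {
            mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gr$dW[[l]]
            mB[[l]] <- beta1 * mB[[l]] + (1 - beta1) * gr$db[[l]]
            vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gr$dW[[l]]^2
            vB[[l]] <- beta2 * vB[[l]] + (1 - beta2) * gr$db[[l]]^2
            mhW <- mW[[l]] / (1 - beta1^step); vhW <- vW[[l]] / (1 - beta2^step)
            mhB <- mB[[l]] / (1 - beta1^step); vhB <- vB[[l]] / (1 - beta2^step)
            net$W[[l]] <- net$W[[l]] - lr * mhW / (sqrt(vhW) + eps)
            net$b[[l]] <- net$b[[l]] - lr * mhB / (sqrt(vhB) + eps)
          } else {  # rmsprop
            vW[[l]] <- 0.9 * vW[[l]] + 0.1 * gr$dW[[l]]^2
            vB[[l]] <- 0.9 * vB[[l]] + 0.1 * gr$db[[l]]^2
            net$W[[l]] <- net$W[[l]] - lr * gr$dW[[l]] / (sqrt(vW[[l]]) + eps)
            net$b[[l]] <- net$b[[l]] - lr * gr$db[[l]] / (sqrt(vB[[l]]) + eps)
          }
        }
      }
    }
    structure(list(net = net, classes = classes), class = "mlpFit")
  })
}

#' @rdname mlpFit
#' @param fit an `mlpFit`.
#' @keywords internal
mlpPredict <- function(fit, X) {
  P <- mlpForward(fit$net, X)$probs
  colnames(P) <- fit$classes
  P
}

# Gaussian radial-basis-function network: one RBF layer with uniform-random
# centers over the training feature ranges, followed by a multinomial
# softmax layer (fitted with nnet::multinom).
rbfFit <- function(X, y, units = 20L, gamma = 0.5, seed = 1L) {
  stopifnot(is.matrix(X), is.factor(y))
  withSeed(seed, {
    lo <- apply(X, 2, min); hi <- apply(X, 2, max)
    centers <- sapply(seq_len(ncol(X)), function(j)
      runif(units, lo[j], hi[j]))
    if (units == 1L) centers <- matrix(centers, nrow = 1L)
    Phi <- rbfTransform(X, centers, gamma)
    df <- data.frame(Phi, .y = y)
    sm <- nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 300,
                         MaxNWts = 5000)
    structure(list(centers = centers, gamma = gamma, classes = levels(y),
                   softmax = sm), class = "rbfFit")
  })
}

rbfTransform <- function(X, centers, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(centers^2), "+") - 2 * X %*% t(centers)
  Phi <- exp(-gamma * pmax(d2, 0))
  colnames(Phi) <- paste0("phi", seq_len(ncol(Phi)))
  Phi
}

rbfPredict <- function(fit, X) {
  Phi <- rbfTransform(X, fit$centers, fit$gamma)
  P <- predict(fit$softmax, newdata = data.frame(Phi), type = "probs")
  if (is.null(dim(P))) {
    # single-row predictions come back as a named probability vector
    P <- matrix(P, nrow = 1L, dimnames = list(NULL, names(P)))
  }
  P[, fit$classes, drop = FALSE]
}

# k-nearest-neighbour probability classifier supporting Euclidean and
# Manhattan metrics (class::knn offers neither Manhattan distance nor
# class-probability output for k > 1, hence in-package).
knnFit <- function(X, y, k = 5L, metric = "euclidean") {
  stopifnot(is.matrix(X), is.factor(y), k >= 1L,
            metric %in% c("euclidean", "manhattan"))
  structure(list(X = X, y = y, k = as.integer(k), metric = metric,
                 classes = levels(y)), class = "knnFit")
}

knnPredict <- function(fit, X) {
  n <- nrow(X); nc <- length(fit$classes)
  P <- matrix(0, n, nc, dimnames = list(NULL, fit$classes))
  yi <- as.integer(fit$y)
  k <- min(fit$k, nrow(fit$X))
  # blocked distance computation keeps memory bounded on large query sets
  blockSize <- max(1L, floor(4e6 / nrow(fit$X)))
  trSq <- rowSums(fit$X^2)
  for (start in seq(1L, n, by = blockSize)) {
    idx <- start:min(start + blockSize - 1L, n)
    Q <- X[idx, , drop = FALSE]
    D <- if (fit$metric == "euclidean") {
      # squared distances suffice for ranking
      outer(rowSums(Q^2), trSq, "+") - 2 * Q %*% t(fit$X)
    } else {
      M <- matrix(0, length(idx), nrow(fit$X))
      for (j in seq_len(ncol(Q)))
        M <- M + abs(outer(Q[, j], fit$X[, j], "-"))
      M
    }
    for (ii in seq_along(idx)) {
      nb <- order(D[ii, ])[seq_len(k)]  # stable: index order on ties
      tab <- tabulate(yi[nb], nbins = nc)
      P[idx[ii], ] <- tab / sum(tab)
    }
  }
  P
}
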