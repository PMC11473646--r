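#' Derive a stage-specific seed from the pipeline seed
#'
#' All randomized components of the pipeline draw their seed from a single
#' pipeline seed mixed with the stage name, so stages are independently
#' reproducible. The rule is a fixed linear-congruential mix of the seed with
#' the character codes of the stage label, reduced modulo 2^31 - 1.
#'
#' @param seed integer pipeline seed.
#' @param stage character stage label, e.g. `"hill"`, `"train"`.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stage), length(stage) == 1L)
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% m
  as.integer((abs(seed) %% m * 48271 + h * 69621 + 1) %% (m - 1) + 1)
}

# Evaluate `expr` under a local RNG seed, restoring global RNG state after.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Percentile with linear interpolation, robust to infinities
#'
#' Linear interpolation between order statistics (the classical type-7 rule),
#' except that when the interpolation weight is exactly 0 or 1 the order
#' statistic itself is returned, so streams containing `Inf` never produce
#' `0 * Inf` artifacts. `NA`/`NaN` values must be removed by the caller.
#'
#' @param x numeric vector (may contain `Inf`/`-Inf`, not `NA`).
#' @param probs probabilities in `[0, 1]`.
#' @return numeric vector of percentiles.
#' @export
linearPercentile <- function(x, probs) {
  stopifnot(!anyNA(x))
  n <- length(x)
  if (n == 0L) return(rep(NA_real_, length(probs)))
  xs <- sort(x)
  vapply(probs, function(p) {
    idx <- (n - 1) * p + 1
    j <- floor(idx)
    g <- idx - j
    if (g <= 0) xs[j] else if (g >= 1) xs[j + 1] else (1 - g) * xs[j] + g * xs[j + 1]
  }, numeric(1))
}

# Linear-interpolated downward threshold crossing time.
# Returns the first time t where y crosses `thr` from above, searching
# forward from index `from`; NA if never crossed.
crossingTime <- function(time, y, thr, from = 1L) {
  n <- length(y)
  if (from > n) return(NA_real_)
  below <- which(y[from:n] <= thr)
  if (length(below) == 0L) return(NA_real_)
  i <- from + below[1L] - 1L
  if (i == from) return(time[i])
  y0 <- y[i - 1L]; y1 <- y[i]
  if (y1 == y0) return(time[i])
  time[i - 1L] + (y0 - thr) / (y0 - y1) * (time[i] - time[i - 1L])
}

# Trapezoidal integral of y over time grid t (non-uniform allowed).
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(t)) / 2
}

fmtCI <- function(median, lo, hi, digits = 2) {
  f <- function(v) formatC(round(v, digits), format = "fg", flag = "#")
  sprintf("%s (%s, %s)", round(median, digits), round(lo, digits),
          round(hi, digits))
}
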