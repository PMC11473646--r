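#' @include AllClasses.R
NULL

#' Hill inhibition fraction
#'
#' Fractional block of an ion current at drug concentration `conc`:
#' \deqn{1 / (1 + (IC_{50} / D)^h)}
#' The zero-dose limit is 0; the result lies in `[0, 1)`.
#'
#' @param ic50 half-inhibition concentration, nM (> 0).
#' @param h Hill coefficient (> 0).
#' @param conc drug concentration, nM (>= 0); vectorized.
#' @return inhibition fraction(s) in `[0, 1)`.
#' @examples
#' hillInhibition(100, 1, 100)  # 0.5 at D = IC50
#' @export
hillInhibition <- function(ic50, h, conc) {
  if (!all(is.finite(ic50)) || !all(is.finite(h)) || any(ic50 <= 0) ||
      any(h <= 0))
    stop("ic50 and h must be finite and strictly positive")
  if (!all(is.finite(conc)) || any(conc < 0))
    stop("concentration must be finite and non-negative")
  ifelse(conc == 0, 0, 1 / (1 + (ic50 / conc)^h))
}

#' Per-channel conductance multipliers at a Cmax multiple
#'
#' Drug block rescales each maximum channel conductance by
#' `1 - inhibition` at `D = multiple x Cmax`. Channels without fitted Hill
#' parameters keep multiplier 1.
#'
#' @param hill named list of Hill parameters per channel; each element a list
#'   (or `HillPosterior` sample row) with `ic50` and `h`. Channels absent from
#'   the list are left unblocked.
#' @param cmax maximal free plasma concentration, nM (> 0).
#' @param multiple concentration multiple of Cmax (default 1; the pipeline
#'   uses 1--4).
#' @return named numeric vector over [tdpChannels] of multipliers in `[0, 1]`.
#' @export
blockProfile <- function(hill, cmax, multiple = 1) {
  stopifnot(is.numeric(cmax), length(cmax) == 1L, is.finite(cmax), cmax > 0,
            is.numeric(multiple), length(multiple) == 1L, multiple >= 0)
  if (length(hill) && (is.null(names(hill)) ||
                       !all(names(hill) %in% tdpChannels)))
    stop("hill must be named by channels from tdpChannels")
  prof <- setNames(rep(1, length(tdpChannels)), tdpChannels)
  for (ch in names(hill)) {
    p <- hill[[ch]]
    prof[ch] <- 1 - hillInhibition(p$ic50, p$h, multiple * cmax)
  }
  prof
}

#' Read a dose-response CSV
#'
#' Expected columns: `drug,channel,conc,block` (header required). `conc` is in
#' nM; `block` is a fraction in `[0, 1]`, or a percent in `[0, 100]` when
#' `percent = TRUE` (values are then divided by 100). Block values within
#' floating-point slack of the bounds are clipped to `[0, 1]`.
#'
#' @param path CSV file path.
#' @param percent logical; `TRUE` when the block column is in percent.
#' @return data.frame of validated records with columns
#'   `drug`, `channel`, `conc`, `block`.
#' @export
readDoseResponse <- function(path, percent = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug", "channel", "conc", "block")
  if (!all(need %in% names(df)))
    stop("dose-response CSV must have columns ", paste(need, collapse = ","))
  df <- df[need]
  if (percent) df$block <- df$block / 100
  bad <- which(!df$channel %in% tdpChannels)
  if (length(bad))
    stop(sprintf("row %d: unknown channel '%s'", bad[1], df$channel[bad[1]]))
  bad <- which(!is.finite(df$conc) | df$conc <= 0)
  if (length(bad))
    stop(sprintf("row %d: concentration must be positive", bad[1]))
  bad <- which(!is.finite(df$block) | df$block < -1e-9 | df$block > 1 + 1e-9)
  if (length(bad))
    stop(sprintf("row %d: block %.4g outside [0, 1]", bad[1], df$block[bad[1]]))
  df$block <- pmin(pmax(df$block, 0), 1)
  df
}

# Log posterior of (log ic50, log h[, log sigma]) under a Gaussian likelihood
# on fractional block. Priors: log-uniform IC50 on [1e-3, 1e7] nM, uniform h
# on (0, 10], half-normal(0.1) on sigma when sampled.
hillLogPost <- function(theta, conc, block, sigma = NULL) {
  logIc50 <- theta[1]; logH <- theta[2]
  if (logIc50 < log(1e-3) || logIc50 > log(1e7)) return(-Inf)
  h <- exp(logH)
  if (h <= 0 || h > 10) return(-Inf)
  if (is.null(sigma)) {
    sig <- exp(theta[3])
    if (sig <= 0 || sig > 5) return(-Inf)
    lprior <- dnorm(sig, 0, 0.1, log = TRUE) + theta[3]  # half-normal + Jacobian
  } else {
    sig <- sigma
    lprior <- 0
  }
  mu <- 1 / (1 + exp(h * (logIc50 - log(conc))))
  # uniform h prior in h-space has Jacobian exp(logH) in log-space
  sum(dnorm(block, mu, sig, log = TRUE)) + logH + lprior
}

#' Fit Hill parameters by adaptive random-walk Metropolis MCMC
#'
#' Samples the posterior of `(log IC50, log h)` (and `log sigma` when the
#' noise sd is not supplied) under a Gaussian likelihood on fractional block.
#' Priors: log-uniform IC50 on `[1e-3, 1e7]` nM; uniform h on `(0, 10]`;
#' half-normal(0.1) on sigma. The proposal scale adapts during burn-in toward
#' an acceptance rate in 0.2--0.5, then is frozen; the post-burn-in chain is
#' thinned to return exactly `nSamples` draws.
#'
#' @param records data.frame of dose-response records for a single drug x
#'   channel (columns `conc`, `block`, and optionally `drug`, `channel`).
#' @param nSamples number of posterior draws to return (default 2000).
#' @param seed integer chain seed (required).
#' @param sigma known noise sd on fractional block, or `NULL` (default) to
#'   sample it.
#' @param burnin burn-in iterations (default 2000).
#' @param thin thinning interval (default 5).
#' @param drug,channel identifiers stored in the result; taken from `records`
#'   when present.
#' @return a [HillPosterior-class]
#' @export
fitHillMCMC <- function(records, nSamples = 2000L, seed, sigma = NULL,
                        burnin = 2000L, thin = 5L,
                        drug = NULL, channel = NULL) {
  if (missing(seed)) stop("a seed is required for reproducible chains")
  conc <- records$conc; block <- records$block
  if (length(unique(conc)) < 2L)
    stop("need at least 2 distinct concentrations to fit a Hill curve")
  if (any(!is.finite(conc)) || any(conc <= 0) ||
      any(!is.finite(block)) || any(block < 0) || any(block > 1))
    stop("invalid dose-response records")
  drug <- drug %||% (if ("drug" %in% names(records)) records$drug[1] else "drug")
  channel <- channel %||%
    (if ("channel" %in% names(records)) records$channel[1] else "IKr")

  npar <- if (is.null(sigma)) 3L else 2L
  withSeed(seed, {
    # crude initialization: concentration nearest half-block, slope 1
    i0 <- which.min(abs(block - 0.5))
    theta <- c(log(conc[i0]), log(1), if (npar == 3L) log(0.1))
    scale <- rep(0.5, npar)
    lp <- hillLogPost(theta, conc, block, sigma)
    nKeep <- as.integer(nSamples)
    nPost <- nKeep * as.integer(thin)
    out <- matrix(NA_real_, nKeep, npar)
    accWindow <- 0L; accTotal <- 0L; kept <- 0L
    nIter <- as.integer(burnin) + nPost
    for (it in seq_len(nIter)) {
      prop <- theta + rnorm(npar) * scale
      lpProp <- hillLogPost(prop, conc, block, sigma)
      if (is.finite(lpProp) && log(runif(1)) < lpProp - lp) {
        theta <- prop; lp <- lpProp
        accWindow <- accWindow + 1L
        if (it > burnin) accTotal <- accTotal + 1L
      }
      if (it <= burnin && it %% 100L == 0L) {
        rate <- accWindow / 100
        if (rate < 0.2) scale <- scale * 0.7
        else if (rate > 0.5) scale <- scale * 1.4
        accWindow <- 0L
      }
      if (it > burnin && (it - burnin) %% thin == 0L) {
        kept <- kept + 1L
        out[kept, ] <- theta
      }
    }
    accRate <- accTotal / nPost
    if (accRate < 0.01)
      stop(sprintf(
        "MCMC chain failed to move (acceptance %.3f): check the data", accRate))
    new("HillPosterior", drug = as.character(drug),
        channel = as.character(channel),
        samples = data.frame(ic50 = exp(out[, 1]), h = exp(out[, 2])),
        chainMeta = list(seed = as.integer(seed), burnin = as.integer(burnin),
                         thin = as.integer(thin), acceptanceRate = accRate,
                         sigma = if (is.null(sigma)) NA_real_ else sigma))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read posterior samples as CSV with a JSON metadata sidecar
#'
#' The CSV layout is `drug,channel,sample_index,ic50_nM,hill`; chain metadata
#' goes to `<path>.meta.json`.
#'
#' @param posteriors a [HillPosterior-class] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeHillPosteriors <- function(posteriors, path) {
  if (is(posteriors, "HillPosterior")) posteriors <- list(posteriors)
  rows <- do.call(rbind, lapply(posteriors, function(p) {
    data.frame(drug = p@drug, channel = p@channel,
               sample_index = seq_len(nrow(p@samples)),
               ic50_nM = p@samples$ic50, hill = p@samples$h)
  }))
  write.csv(rows, path, row.names = FALSE)
  meta <- lapply(posteriors, function(p)
    c(list(drug = p@drug, channel = p@channel), p@chainMeta))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
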