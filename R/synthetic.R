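#' @include biomarkers.R
NULL

#' Generate noisy Hill dose-response records with known truth
#'
#' Block values follow the Hill curve at the given concentrations plus
#' Gaussian noise, clipped to `[0, 1]`. The generating parameters are
#' returned alongside the records so recovery tests never re-estimate truth.
#'
#' @param ic50,h true Hill parameters.
#' @param conc concentration grid, nM; must span the true IC50 (at least one
#'   point on each side).
#' @param replicates measurements per concentration (default 3).
#' @param noiseSd Gaussian noise sd on fractional block (default 0.03).
#' @param seed integer seed.
#' @param drug,channel identifiers for the records.
#' @return list with `records` (data.frame `drug,channel,conc,block`) and
#'   `truth` (list `ic50`, `h`).
#' @export
genDoseResponse <- function(ic50, h, conc, replicates = 3L, noiseSd = 0.03,
                            seed, drug = "synthetic", channel = "IKr") {
  if (missing(seed)) stop("a seed is required")
  if (!any(conc < ic50) || !any(conc > ic50))
    stop("concentration grid must span the true IC50")
  withSeed(seed, {
    cc <- rep(conc, each = replicates)
    mu <- hillInhibition(ic50, h, cc)
    block <- pmin(pmax(mu + rnorm(length(cc), 0, noiseSd), 0), 1)
    list(records = data.frame(drug = drug, channel = channel,
                              conc = cc, block = block),
         truth = list(ic50 = ic50, h = h, noiseSd = noiseSd))
  })
}

# Solve the double-exponential shape exp(-u) - exp(-u/k) for the ratio of the
# 90% to the 50% peak-to-recovery duration; monotone in k on (0, 1).
caShapeDurations <- function(k) {
  f <- function(u) exp(-u) - exp(-u / k)
  upk <- -k * log(k) / (1 - k)        # analytic peak location
  fpk <- f(upk)
  dur <- function(frac) {
    thr <- fpk * (1 - frac)
    uniroot(function(u) f(u) - thr, c(upk, upk + 200 * (1 + k)),
            tol = 1e-12)$root - upk
  }
  c(d50 = dur(0.5), d90 = dur(0.9))
}

#' Generate a one-beat waveform with analytically known biomarkers
#'
#' Builds Vm as a parametric beat -- flat rest, linear 1 ms upstroke,
#' piecewise-linear monotone repolarization whose 50% and 90% crossings land
#' exactly on the requested APD50/APD90 -- and Cai as a double-exponential
#' transient whose peak-to-recovery durations solve exactly to CaD50/CaD90.
#' The six qNet currents are low-order polynomial templates with closed-form
#' integrals. Returns the exact biomarker truths alongside the trace.
#'
#' @param apd50,apd90 target AP durations, ms (`apd90 > apd50`).
#' @param cad50,cad90 target calcium-transient durations, ms; the ratio
#'   `cad90/cad50` must lie in the double-exponential's attainable range
#'   (about 2.3--3.3).
#' @param vrest,vpeak resting and peak Vm, mV.
#' @param caDiastole,caAmp diastolic calcium and transient amplitude (mM).
#' @param cycleLength ms (default 2000).
#' @param dt output step, ms (default 0.1).
#' @param qnetTarget target analytic qNet (A/F x ms) shaping the current
#'   templates.
#' @return list with `trace` (a single-beat [SimulationTrace-class]) and
#'   `truth` (named biomarker values; `qInward` is 2 against the trace's own
#'   control by construction).
#' @export
genWaveform <- function(apd50 = 220, apd90 = 300, cad50 = 200, cad90 = 550,
                        vrest = -85, vpeak = 40, caDiastole = 1e-4,
                        caAmp = 5e-4, cycleLength = 2000, dt = 0.1,
                        qnetTarget = 300) {
  if (apd90 <= apd50 || apd50 <= 0) stop("need apd90 > apd50 > 0")
  if (cad90 <= cad50 || cad50 <= 0) stop("need cad90 > cad50 > 0")
  amp <- vpeak - vrest
  if (amp <= 30) stop("AP amplitude must exceed 30 mV")
  tUp <- 1; tpk <- tUp
  time <- seq(0, cycleLength, by = dt)

  # Vm: kinks exactly on the 50% and 90% crossing times
  s1 <- -0.5 * amp / apd50
  s2 <- -0.4 * amp / (apd90 - apd50)
  tEnd <- tpk + apd90 + 0.1 * amp / abs(s2)
  vm <- ifelse(time <= 0, vrest,
        ifelse(time <= tpk, vrest + amp * time / tUp,
        ifelse(time <= tpk + apd50, vpeak + s1 * (time - tpk),
        ifelse(time <= tpk + apd90,
               vpeak - 0.5 * amp + s2 * (time - tpk - apd50),
        ifelse(time <= tEnd,
               vpeak - 0.9 * amp + s2 * (time - tpk - apd90), vrest)))))

  # Cai: solve shape parameter k for the duration ratio, then scale time
  ratio <- cad90 / cad50
  lims <- c(1e-4, 0.9999)
  rlo <- caShapeDurations(lims[2]); rhi <- caShapeDurations(lims[1])
  if (ratio <= rlo["d90"] / rlo["d50"] || ratio >= rhi["d90"] / rhi["d50"])
    stop(sprintf("cad90/cad50 = %.3f outside attainable range (%.3f, %.3f)",
                 ratio, rlo["d90"] / rlo["d50"], rhi["d90"] / rhi["d50"]))
  k <- uniroot(function(kk) { d <- caShapeDurations(kk); d["d90"] / d["d50"] - ratio },
               lims, tol = 1e-12)$root
  d <- caShapeDurations(k)
  tauD <- cad50 / d[["d50"]]
  tauR <- k * tauD
  upk <- -k * log(k) / (1 - k) * tauD
  shape <- function(t) exp(-t / tauD) - exp(-t / tauR)
  fpk <- shape(upk)
  tCa0 <- tpk  # transient starts at the AP peak
  cai <- ifelse(time <= tCa0, caDiastole,
                caDiastole + caAmp * shape(time - tCa0) / fpk)

  # currents: constant templates (trapezoid-exact) whose six-way sum
  # integrates to exactly qnetTarget over one cycle length
  cur <- matrix(0, length(time), length(tdpChannels),
                dimnames = list(NULL, tdpChannels))
  s0 <- qnetTarget / cycleLength
  weights <- c(INaL = -0.5, ICaL = -1, IKr = 1.5, IKs = 0.4, IK1 = 0.4,
               Ito = 0.2)  # sums to 1
  for (ch in qNetCurrents) cur[, ch] <- s0 * weights[[ch]]
  cur[, "INa"] <- -0.1 * abs(s0)

  trace <- new("SimulationTrace", time = time, Vm = vm, Cai = cai,
               currents = cur, beatStarts = 1L, cycleLength = cycleLength)
  truth <- c(dVmdt_repol = max(s1, s2), dVmdt_max = amp / tUp,
             Vm_resting = vrest,
             APD90 = apd90, APD50 = apd50, APD_tri = apd90 - apd50,
             CaD90 = cad90, CaD50 = cad50, Ca_tri = cad90 - cad50,
             Ca_diastole = caDiastole, qInward = 2, qNet = qnetTarget)
  list(trace = trace, truth = truth)
}

#' Specification for the synthetic feature table
#'
#' Defaults mirror the study design: 3 risk classes, 4 training drugs per
#' class (12 train) and 5/6/5 test drugs (16 test), 200 samples per drug at
#' desk scale (2000 at paper scale). Class mean vectors are plausible
#' biomarker values; per-drug offsets and within-drug noise are Gaussian.
#'
#' @param samplesPerDrug rows per drug (default 200).
#' @param paperScale logical; `TRUE` sets 2000 samples per drug.
#' @param separation multiplier on the between-class mean differences
#'   (default 1; larger is more separable).
#' @param noiseScale multiplier on within-drug sds (default 1).
#' @param drugOffsetScale multiplier on per-drug mean offsets (default 1).
#' @param labelNoise fraction of training rows with randomly reassigned
#'   labels (default 0).
#' @param nNoiseFeatures extra pure-noise features, standard normal and
#'   independent of the class (default 0).
#' @param trainPerClass,testPerClass named integer vectors of drugs per risk
#'   class; defaults mirror the 12-train / 16-test drug allocation.
#' @return a `FeatureSpec` list.
#' @export
featureSpec <- function(samplesPerDrug = 200L, paperScale = FALSE,
                        separation = 1, noiseScale = 1, drugOffsetScale = 1,
                        labelNoise = 0, nNoiseFeatures = 0L,
                        trainPerClass = c(high = 4L, intermediate = 4L,
                                          low = 4L),
                        testPerClass = c(high = 4L, intermediate = 7L,
                                         low = 5L)) {
  if (paperScale) samplesPerDrug <- 2000L
  stopifnot(samplesPerDrug >= 1L, separation >= 0, noiseScale >= 0,
            labelNoise >= 0, labelNoise <= 1, nNoiseFeatures >= 0L)
  base <- c(dVmdt_repol = 0.4, dVmdt_max = 120, Vm_resting = -88,
            APD90 = 280, APD50 = 220, APD_tri = 60,
            CaD90 = 430, CaD50 = 260, Ca_tri = 170,
            Ca_diastole = 1e-4, qInward = 1.9, qNet = 600)
  # class effects relative to the low-risk base, scaled by `separation`
  effHigh <- c(0.35, -25, 1.5, 90, 65, 25, 90, 55, 35, 2.5e-5, -0.15, -450)
  effInt  <- c(0.15, -10, 0.7, 45, 30, 15, 45, 25, 20, 1.0e-5, -0.40, -250)
  classMeans <- cbind(high = base + separation * effHigh,
                      intermediate = base + separation * effInt,
                      low = base)
  sdWithin <- c(0.08, 8, 0.8, 18, 14, 7, 22, 14, 10, 8e-6, 0.08, 90)
  names(sdWithin) <- names(base)
  structure(list(classMeans = classMeans,
                 sdWithin = sdWithin * noiseScale,
                 sdDrug = sdWithin * 0.6 * drugOffsetScale,
                 trainPerClass = trainPerClass,
                 testPerClass = testPerClass,
                 samplesPerDrug = as.integer(samplesPerDrug),
                 labelNoise = labelNoise,
                 nNoiseFeatures = as.integer(nNoiseFeatures)),
            class = "FeatureSpec")
}

#' Generate a synthetic biomarker feature table with known truth
#'
#' Per drug, samples are drawn from a Gaussian with mean = class mean +
#' per-drug offset and diagonal within-drug covariance; labels follow the
#' class assignment with optional label noise on training rows; split tags
#' follow the drug allocation in the spec. Pure-noise features (standard
#' normal, class-independent) can be appended for elimination diagnostics.
#'
#' @param spec a [featureSpec()].
#' @param seed integer seed.
#' @return list with `table` (a [BiomarkerExperiment-class]) and `truth`
#'   (class means, per-drug offsets, names of noise features).
#' @export
genFeatureTable <- function(spec = featureSpec(), seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(inherits(spec, "FeatureSpec"))
  classes <- colnames(spec$classMeans)
  p <- nrow(spec$classMeans)
  featNames <- rownames(spec$classMeans)
  noiseNames <- if (spec$nNoiseFeatures > 0)
    paste0("noise", seq_len(spec$nNoiseFeatures)) else character()
  withSeed(seed, {
    drugs <- list()
    for (cls in classes) {
      nTr <- spec$trainPerClass[[cls]]; nTe <- spec$testPerClass[[cls]]
      ids <- sprintf("%s_%s%02d", cls, c(rep("train", nTr), rep("test", nTe)),
                     c(seq_len(nTr), seq_len(nTe)))
      for (i in seq_along(ids))
        drugs[[ids[i]]] <- list(class = cls,
                                split = if (i <= nTr) "train" else "test")
    }
    offsets <- lapply(drugs, function(d) rnorm(p, 0, spec$sdDrug))
    X <- NULL; drug <- risk <- split <- character()
    for (id in names(drugs)) {
      d <- drugs[[id]]
      mu <- spec$classMeans[, d$class] + offsets[[id]]
      n <- spec$samplesPerDrug
      Xi <- MASS::mvrnorm(n, mu, diag(spec$sdWithin^2, p))
      if (n == 1L) Xi <- matrix(Xi, nrow = 1L)
      X <- rbind(X, Xi)
      drug <- c(drug, rep(id, n))
      risk <- c(risk, rep(d$class, n))
      split <- c(split, rep(d$split, n))
    }
    colnames(X) <- featNames
    if (spec$nNoiseFeatures > 0) {
      Z <- matrix(rnorm(nrow(X) * spec$nNoiseFeatures), nrow(X),
                  dimnames = list(NULL, noiseNames))
      X <- cbind(X, Z)
    }
    if (spec$labelNoise > 0) {
      tr <- which(split == "train")
      flip <- tr[runif(length(tr)) < spec$labelNoise]
      risk[flip] <- sample(classes, length(flip), replace = TRUE)
    }
    rownames(X) <- sprintf("s%05d", seq_len(nrow(X)))
    list(table = BiomarkerExperiment(X, drug = drug, risk = risk,
                                     split = split),
         truth = list(classMeans = spec$classMeans, drugOffsets = offsets,
                      noiseFeatures = noiseNames))
  })
}
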