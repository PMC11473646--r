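#' @include ionic-model.R
NULL

#' Pacing protocol
#'
#' @param cycleLength basic cycle length, ms (default 2000, the protocol of
#'   the pipeline).
#' @param nPrepace drug-free conditioning beats (default 1000).
#' @param nDrugBeats beats under the drug block profile (default 1000).
#' @param nRecorded number of final drug beats returned on the output grid
#'   (default 250); must not exceed `nDrugBeats`.
#' @param stimAmp stimulus amplitude, A/F (default -80, rectangular).
#' @param stimDur stimulus duration, ms (default 0.5).
#' @param dt uniform output time step, ms (default 0.1).
#' @return a `PacingProtocol` list.
#' @export
pacingProtocol <- function(cycleLength = 2000, nPrepace = 1000,
                           nDrugBeats = 1000, nRecorded = 250,
                           stimAmp = -80, stimDur = 0.5, dt = 0.1) {
  stopifnot(cycleLength > 0, stimDur > 0, dt > 0,
            nPrepace >= 0, nDrugBeats >= 1, nRecorded >= 1)
  if (nRecorded > nDrugBeats)
    stop("nRecorded must not exceed nDrugBeats")
  structure(list(cycleLength = cycleLength, nPrepace = as.integer(nPrepace),
                 nDrugBeats = as.integer(nDrugBeats),
                 nRecorded = as.integer(nRecorded), stimAmp = stimAmp,
                 stimDur = stimDur, dt = dt),
            class = "PacingProtocol")
}

# Integrate one beat; returns final state, and (if recorded) the dense output.
integrateBeat <- function(model, state, mult, protocol, record) {
  cl <- protocol$cycleLength; dt <- protocol$dt
  t1 <- if (record) seq(0, protocol$stimDur, by = dt) else
    c(0, protocol$stimDur)
  t2 <- if (record) seq(protocol$stimDur, cl, by = dt) else
    c(protocol$stimDur, cl)
  if (record && abs(t2[length(t2)] - cl) > 1e-9) t2 <- c(t2, cl)
  seg1 <- deSolve::lsoda(state, t1, model$rhs,
                         model$parms0(mult, protocol$stimAmp, protocol$stimDur),
                         rtol = 1e-6, atol = 1e-8)
  s1 <- seg1[nrow(seg1), 1 + seq_along(state)]
  seg2 <- deSolve::lsoda(s1, t2, model$rhs, model$parms0(mult, 0, -1),
                         rtol = 1e-6, atol = 1e-8)
  endState <- seg2[nrow(seg2), 1 + seq_along(state)]
  if (any(!is.finite(endState)))
    stop("solver divergence: non-finite state at end of beat")
  out <- NULL
  if (record) {
    both <- rbind(seg1[-nrow(seg1), , drop = FALSE], seg2)
    # drop the duplicated cl point if the grid landed exactly on cl twice
    keep <- !duplicated(both[, "time"])
    out <- both[keep, , drop = FALSE]
  }
  list(state = endState, out = out)
}

#' Pace a myocyte model under a drug block profile
#'
#' Runs `nPrepace` conditioning beats with all conductance multipliers 1,
#' then `nDrugBeats` beats under `block`, and returns the last `nRecorded`
#' drug beats resampled to the uniform output grid. Deterministic for fixed
#' inputs.
#'
#' @param model an `IonicModel` (see [bundledModel()]).
#' @param protocol a [pacingProtocol()].
#' @param block named conductance multipliers over [tdpChannels] (see
#'   [blockProfile()]); default all 1 (control).
#' @return a [SimulationTrace-class] of the recorded beats.
#' @export
runPacing <- function(model, protocol = pacingProtocol(),
                      block = setNames(rep(1, 7), tdpChannels)) {
  stopifnot(inherits(protocol, "PacingProtocol"))
  if (!all(tdpChannels %in% names(block)))
    stop("block must name all seven channels")
  if (any(!is.finite(block)) || any(block < 0) || any(block > 1))
    stop("conductance multipliers must lie in [0, 1]")
  ones <- setNames(rep(1, 7), tdpChannels)
  state <- model$state0
  for (b in seq_len(protocol$nPrepace)) {
    res <- tryCatch(integrateBeat(model, state, ones, protocol, FALSE),
                    error = function(e)
                      stop(sprintf("prepace beat %d: %s", b, conditionMessage(e))))
    state <- res$state
  }
  nSkip <- protocol$nDrugBeats - protocol$nRecorded
  recorded <- vector("list", protocol$nRecorded)
  for (b in seq_len(protocol$nDrugBeats)) {
    rec <- b > nSkip
    res <- tryCatch(integrateBeat(model, state, block[tdpChannels], protocol, rec),
                    error = function(e)
                      stop(sprintf("drug beat %d: %s", b, conditionMessage(e))))
    state <- res$state
    if (rec) recorded[[b - nSkip]] <- res$out
  }
  assembleTrace(recorded, model, protocol)
}

assembleTrace <- function(recorded, model, protocol) {
  cl <- protocol$cycleLength
  beatStarts <- integer(length(recorded))
  rows <- 0L
  pieces <- vector("list", length(recorded))
  for (i in seq_along(recorded)) {
    seg <- recorded[[i]]
    if (i < length(recorded)) seg <- seg[-nrow(seg), , drop = FALSE]
    beatStarts[i] <- rows + 1L
    seg[, "time"] <- seg[, "time"] + (i - 1L) * cl
    rows <- rows + nrow(seg)
    pieces[[i]] <- seg
  }
  m <- do.call(rbind, pieces)
  vmName <- model$observables$Vm; caiName <- model$observables$Cai
  new("SimulationTrace",
      time = as.numeric(m[, "time"]),
      Vm = as.numeric(m[, vmName]),
      Cai = as.numeric(m[, caiName]),
      currents = m[, tdpChannels, drop = FALSE],
      beatStarts = beatStarts,
      cycleLength = cl)
}

# Per-beat morphology: stimulus onset is the first sample of the beat; the
# pre-stimulus reference voltage is the value at onset (the model is sampled
# at the instant the stimulus starts). Returns peak info and fractional
# repolarization crossing times (absolute, ms).
beatMorphology <- function(time, vm) {
  vrest <- vm[1L]
  ipk <- which.max(vm)
  vpk <- vm[ipk]
  amp <- vpk - vrest
  thr <- function(f) vpk - f * amp
  list(vrest = vrest, ipk = ipk, vpk = vpk, amp = amp,
       t30 = crossingTime(time, vm, thr(0.3), from = ipk),
       t50 = crossingTime(time, vm, thr(0.5), from = ipk),
       t90 = crossingTime(time, vm, thr(0.9), from = ipk))
}

#' Times of 30/50/90% repolarization of a beat
#'
#' Crossing times (ms, on the beat's own time axis) where Vm falls through
#' `Vpeak - f (Vpeak - Vrest)` for `f` = 0.3, 0.5, 0.9, by linear
#' interpolation; `Vrest` is the pre-stimulus voltage of the same beat. A
#' threshold never crossed yields `NA`.
#'
#' @param beat a single-beat [SimulationTrace-class] (see [traceBeat()]).
#' @return named numeric `c(t30, t50, t90)`, possibly containing `NA`.
#' @export
repolarizationFractions <- function(beat) {
  stopifnot(is(beat, "SimulationTrace"), nBeats(beat) == 1L)
  m <- beatMorphology(beat@time, beat@Vm)
  if (m$amp < 30 || m$vpk < 0)
    stop("no identifiable depolarization peak: beat is a depolarization failure")
  c(t30 = m$t30, t50 = m$t50, t90 = m$t90)
}

# Windowed maximum repolarization-phase dVm/dt of one beat, following the
# selection rule: full repolarizers use [t30, t90]; partial (>=30% but <90%)
# use [t30, end]; minimal (<30%) use [peak, end].
beatRepolRate <- function(time, vm) {
  m <- beatMorphology(time, vm)
  failed <- (m$vpk < 0) || (m$amp < 30)
  if (failed)
    return(list(rate = NA_real_, category = NA_character_, failed = TRUE))
  if (!is.na(m$t90)) { lo <- m$t30; hi <- m$t90; cat <- "full" }
  else if (!is.na(m$t30)) { lo <- m$t30; hi <- time[length(time)]; cat <- "partial" }
  else { lo <- time[m$ipk]; hi <- time[length(time)]; cat <- "minimal" }
  idx <- which(time >= lo & time <= hi)
  if (length(idx) < 2L) idx <- seq(max(1L, m$ipk), length(time))
  dv <- diff(vm[idx]) / diff(time[idx])
  list(rate = max(dv), category = cat, failed = FALSE)
}

#' Select the analysis beat by the maximum-repolarization-rate rule
#'
#' For every recorded beat the maximum dVm/dt is computed inside a window set
#' by its repolarization extent -- full repolarizers (>= 90%): between the 30%
#' and 90% crossings; partial (>= 30%, < 90%): from the 30% crossing to beat
#' end; minimal (< 30%): from the Vm peak to beat end. Beats that fail to
#' depolarize (peak Vm < 0 mV or amplitude < 30 mV) are omitted. The
#' non-failed beat with the highest windowed rate is selected; ties break to
#' the earliest beat.
#'
#' @param trace a [SimulationTrace-class] with >= 1 recorded beat.
#' @return a [BeatSelection-class]
#' @export
selectBeat <- function(trace) {
  stopifnot(is(trace, "SimulationTrace"))
  nb <- nBeats(trace)
  if (nb < 1L) stop("trace has no recorded beats")
  rates <- numeric(nb); cats <- character(nb); failed <- logical(nb)
  for (i in seq_len(nb)) {
    b <- traceBeat(trace, i)
    res <- beatRepolRate(b@time, b@Vm)
    rates[i] <- res$rate; cats[i] <- res$category; failed[i] <- res$failed
  }
  if (all(failed))
    stop("no analyzable AP: every recorded beat failed to depolarize")
  cand <- which(!failed)
  sel <- cand[which.max(rates[cand])]
  new("BeatSelection", selected = as.integer(sel), rates = rates,
      category = cats, failed = failed)
}

#' Export a trace as CSV
#'
#' Columns: `time_ms,Vm_mV,Cai` plus the seven named currents (A/F).
#' @param trace a [SimulationTrace-class]
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrace <- function(trace, path) {
  df <- data.frame(time_ms = trace@time, Vm_mV = trace@Vm, Cai = trace@Cai)
  df <- cbind(df, as.data.frame(trace@currents))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
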