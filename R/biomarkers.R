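#' @include pacing.R
NULL

#' Duration from signal peak to fractional recovery
#'
#' Time (ms) from the signal peak to the linear-interpolated crossing of
#' `peak - fraction * (peak - baseline)`, where the baseline is the
#' pre-stimulus value (the first sample of the beat). Used for APD50/APD90 on
#' Vm and CaD50/CaD90 on the calcium transient.
#'
#' @param time,signal one-beat time grid (ms) and signal values.
#' @param fraction recovery fraction, typically 0.5 or 0.9.
#' @return duration in ms, or `NA` when the threshold is never crossed.
#' @export
durationAtFraction <- function(time, signal, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  base <- signal[1L]
  ipk <- which.max(signal)
  thr <- signal[ipk] - fraction * (signal[ipk] - base)
  tc <- crossingTime(time, signal, thr, from = ipk)
  if (is.na(tc)) NA_real_ else tc - time[ipk]
}

#' Maximum upstroke and repolarization-window rates of a beat
#'
#' `dVmdt_max` is the maximum finite-difference dVm/dt between stimulus onset
#' and the Vm peak; `dVmdt_repol` is the windowed repolarization-phase
#' maximum used by [selectBeat()].
#'
#' @param beat a single-beat [SimulationTrace-class].
#' @return named numeric `c(dVmdt_max, dVmdt_repol)` in mV/ms.
#' @export
upstrokeAndRepolRates <- function(beat) {
  stopifnot(is(beat, "SimulationTrace"), nBeats(beat) == 1L)
  time <- beat@time; vm <- beat@Vm
  rep <- beatRepolRate(time, vm)
  if (rep$failed) stop("beat failed to depolarize; no rates defined")
  ipk <- which.max(vm)
  up <- if (ipk >= 2L) max(diff(vm[1:ipk]) / diff(time[1:ipk])) else NA_real_
  c(dVmdt_max = up, dVmdt_repol = rep$rate)
}

#' Resting membrane potential and diastolic calcium of a beat
#'
#' `Vm_resting` is the mean Vm over the `preMs` milliseconds up to and
#' including the stimulus onset (for beats recorded from onset, the onset
#' sample); `Ca_diastole` is the minimum Cai within the beat.
#'
#' @param beat a single-beat [SimulationTrace-class].
#' @param preMs pre-stimulus averaging window, ms (default 10; truncated to
#'   the available pre-stimulus segment).
#' @return named numeric `c(Vm_resting, Ca_diastole)`.
#' @export
restingAndDiastolic <- function(beat, preMs = 10) {
  stopifnot(is(beat, "SimulationTrace"), nBeats(beat) == 1L)
  onset <- beat@beatStarts[1L]
  pre <- which(beat@time >= beat@time[onset] - preMs &
               seq_along(beat@time) <= onset)
  if (length(pre) < 1L) stop("beat has no pre-stimulus segment")
  c(Vm_resting = mean(beat@Vm[pre]), Ca_diastole = min(beat@Cai))
}

#' qNet: net charge of six currents over one cycle length
#'
#' Trapezoidal integral of `INaL + ICaL + IKr + IKs + IK1 + Ito` from the
#' stimulus onset over exactly one basic cycle length. Units are A/F x ms
#' (divide by 1000 for uC/uF).
#'
#' @param beat a single-beat [SimulationTrace-class] carrying all six
#'   currents.
#' @param cycleLength integration span, ms; defaults to the trace's cycle
#'   length.
#' @return qNet in A/F x ms.
#' @export
qNet <- function(beat, cycleLength = beat@cycleLength) {
  stopifnot(is(beat, "SimulationTrace"), nBeats(beat) == 1L)
  t0 <- beat@time[beat@beatStarts[1L]]
  idx <- which(beat@time >= t0 & beat@time <= t0 + cycleLength + 1e-9)
  if (beat@time[idx[length(idx)]] < t0 + cycleLength - 1e-9)
    stop("trace grid shorter than one cycle length")
  total <- rowSums(beat@currents[idx, qNetCurrents, drop = FALSE])
  trapz(beat@time[idx], total)
}

#' qInward: drug/control AUC ratios of the inward currents
#'
#' Sum of the drug/control AUC ratios of ICaL and INaL over one cycle length
#' (AUC by trapezoid). As printed, the sum carries no 1/2 factor, so a drug
#' beat identical to control gives exactly 2; `halved = TRUE` selects the
#' averaged variant used elsewhere in the CiPA literature.
#'
#' @param drugBeat,controlBeat single-beat [SimulationTrace-class] objects on
#'   compatible grids.
#' @param halved logical; divide the sum by 2 (default `FALSE`).
#' @return dimensionless qInward.
#' @export
qInward <- function(drugBeat, controlBeat, halved = FALSE) {
  stopifnot(is(drugBeat, "SimulationTrace"), is(controlBeat, "SimulationTrace"))
  auc <- function(b, ch) trapz(b@time, b@currents[, ch])
  ratios <- vapply(c("ICaL", "INaL"), function(ch) {
    den <- auc(controlBeat, ch)
    if (den == 0) stop("degenerate control: zero AUC for ", ch)
    auc(drugBeat, ch) / den
  }, numeric(1))
  s <- sum(ratios)
  if (halved) s / 2 else s
}

#' Extract the twelve biomarkers from a drug beat and its control beat
#'
#' Populates the full [tdpBiomarkers] vector: repolarization and upstroke
#' rates, resting potential, AP and calcium-transient durations at 50/90%
#' with their triangulation differences, diastolic calcium, qInward and qNet.
#' Any missing component (e.g. a threshold never crossed) marks the sample as
#' dropped, mirroring the omission of failed APs.
#'
#' @param drugBeat selected drug beat, a single-beat [SimulationTrace-class].
#' @param controlBeat matched drug-free beat.
#' @param cycleLength ms; defaults to the drug beat's cycle length.
#' @param qinwardHalved passed to [qInward()].
#' @return named numeric vector over [tdpBiomarkers], or `NULL` (with a
#'   warning naming the reason) when the sample must be dropped.
#' @export
extractBiomarkers <- function(drugBeat, controlBeat,
                              cycleLength = drugBeat@cycleLength,
                              qinwardHalved = FALSE) {
  res <- tryCatch({
    rates <- upstrokeAndRepolRates(drugBeat)
    rest <- restingAndDiastolic(drugBeat)
    apd90 <- durationAtFraction(drugBeat@time, drugBeat@Vm, 0.9)
    apd50 <- durationAtFraction(drugBeat@time, drugBeat@Vm, 0.5)
    cad90 <- durationAtFraction(drugBeat@time, drugBeat@Cai, 0.9)
    cad50 <- durationAtFraction(drugBeat@time, drugBeat@Cai, 0.5)
    v <- c(dVmdt_repol = unname(rates["dVmdt_repol"]),
           dVmdt_max = unname(rates["dVmdt_max"]),
           Vm_resting = unname(rest["Vm_resting"]),
           APD90 = apd90, APD50 = apd50, APD_tri = apd90 - apd50,
           CaD90 = cad90, CaD50 = cad50, Ca_tri = cad90 - cad50,
           Ca_diastole = unname(rest["Ca_diastole"]),
           qInward = qInward(drugBeat, controlBeat, halved = qinwardHalved),
           qNet = qNet(drugBeat, cycleLength))
    v[tdpBiomarkers]
  }, error = function(e) {
    warning("sample dropped: ", conditionMessage(e), call. = FALSE)
    NULL
  })
  if (!is.null(res) && anyNA(res)) {
    missing <- names(res)[is.na(res)]
    warning("sample dropped: missing biomarker(s) ",
            paste(missing, collapse = ", "), call. = FALSE)
    return(NULL)
  }
  res
}
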