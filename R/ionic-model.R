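#' @include AllClasses.R
NULL

# The bundled model is a reduced Hodgkin-Huxley-style human ventricular
# myocyte: seven drug-scalable currents (INa, INaL, ICaL, IKr, IKs, IK1, Ito)
# plus a fixed background leak, and a two-compartment calcium subsystem
# (cytosol + SR) with ICaL-graded SR release. It is parameterized for
# plausible morphology (resting ~ -88 mV, APD90 ~ 150-400 ms at CL 2000 ms,
# decaying calcium transient), not as a reproduction of any published
# parameterization. Any model satisfying the same contract (see
# `makeIonicModel`) can be plugged into `runPacing`.

sigm <- function(v, vh, k) 1 / (1 + exp(-(v - vh) / k))

# Steady-state gating values at voltage v (activation k > 0, inactivation k < 0)
bundledGates <- function(v, p) {
  c(m  = sigm(v, p$m_vh,  p$m_k),
    hh = sigm(v, p$h_vh,  p$h_k),
    hL = sigm(v, p$hL_vh, p$hL_k),
    d  = sigm(v, p$d_vh,  p$d_k),
    f  = sigm(v, p$f_vh,  p$f_k),
    xr = sigm(v, p$xr_vh, p$xr_k),
    xs = sigm(v, p$xs_vh, p$xs_k),
    r  = sigm(v, p$r_vh,  p$r_k),
    s  = sigm(v, p$s_vh,  p$s_k))
}

bundledTaus <- function(v, p) {
  c(m  = p$tau_m,
    hh = p$tau_h_min + p$tau_h_amp * sigm(v, p$tau_h_vh, -p$tau_h_k),
    hL = p$tau_hL,
    d  = p$tau_d,
    f  = p$tau_f,
    xr = p$tau_xr,
    xs = p$tau_xs,
    r  = p$tau_r,
    s  = p$tau_s)
}

# Instantaneous currents at state (A/F); mult = named conductance multipliers.
bundledCurrents <- function(v, g, cai, p, mult) {
  ina  <- mult[["INa"]]  * p$gNa  * g[["m"]]^3 * g[["hh"]] * (v - p$ENa)
  inal <- mult[["INaL"]] * p$gNaL * sigm(v, p$mL_vh, p$mL_k) * g[["hL"]] *
          (v - p$ENa)
  ical <- mult[["ICaL"]] * p$gCaL * g[["d"]] * g[["f"]] * (v - p$ECa)
  ikr  <- mult[["IKr"]]  * p$gKr  * g[["xr"]] * sigm(v, p$rKr_vh, -p$rKr_k) *
          (v - p$EK)
  iks  <- mult[["IKs"]]  * p$gKs  * g[["xs"]]^2 * (v - p$EK)
  ik1  <- mult[["IK1"]]  * p$gK1  * sigm(v, p$k1_vh, -p$k1_k) * (v - p$EK)
  ito  <- mult[["Ito"]]  * p$gto  * g[["r"]] * g[["s"]] * (v - p$EK)
  c(INa = ina, INaL = inal, ICaL = ical, IKr = ikr, IKs = iks,
    IK1 = ik1, Ito = ito)
}

# Right-hand side, written with inline scalar arithmetic (no helper calls or
# named intermediates) because it sits in the integrator's hot loop.
bundledRHS <- function(t, state, parms) {
  p <- parms$p
  mult <- parms$mult
  istim <- if (t < parms$stimEnd) parms$stimAmp else 0
  v <- state[[1]]
  m <- state[[2]]; hh <- state[[3]]; hL <- state[[4]]; d <- state[[5]]
  f <- state[[6]]; xr <- state[[7]]; xs <- state[[8]]; r <- state[[9]]
  s <- state[[10]]
  cai <- state[[11]]; casr <- state[[12]]

  ina  <- mult[[1L]] * p$gNa  * m * m * m * hh * (v - p$ENa)
  inal <- mult[[2L]] * p$gNaL * hL * (v - p$ENa) /
          (1 + exp(-(v - p$mL_vh) / p$mL_k))
  ical <- mult[[3L]] * p$gCaL * d * f * (v - p$ECa)
  ikr  <- mult[[4L]] * p$gKr  * xr * (v - p$EK) /
          (1 + exp((v - p$rKr_vh) / p$rKr_k))
  iks  <- mult[[5L]] * p$gKs  * xs * xs * (v - p$EK)
  ik1  <- mult[[6L]] * p$gK1  * (v - p$EK) / (1 + exp((v - p$k1_vh) / p$k1_k))
  ito  <- mult[[7L]] * p$gto  * r * s * (v - p$EK)
  ileak <- p$gLeak * (v - p$ELeak)
  dv <- -(ina + inal + ical + ikr + iks + ik1 + ito + ileak + istim)

  dm  <- (1 / (1 + exp(-(v - p$m_vh)  / p$m_k))  - m)  / p$tau_m
  tauh <- p$tau_h_min + p$tau_h_amp / (1 + exp((v - p$tau_h_vh) / p$tau_h_k))
  dhh <- (1 / (1 + exp(-(v - p$h_vh)  / p$h_k))  - hh) / tauh
  dhL <- (1 / (1 + exp(-(v - p$hL_vh) / p$hL_k)) - hL) / p$tau_hL
  dd  <- (1 / (1 + exp(-(v - p$d_vh)  / p$d_k))  - d)  / p$tau_d
  df  <- (1 / (1 + exp(-(v - p$f_vh)  / p$f_k))  - f)  / p$tau_f
  dxr <- (1 / (1 + exp(-(v - p$xr_vh) / p$xr_k)) - xr) / p$tau_xr
  dxs <- (1 / (1 + exp(-(v - p$xs_vh) / p$xs_k)) - xs) / p$tau_xs
  dr  <- (1 / (1 + exp(-(v - p$r_vh)  / p$r_k))  - r)  / p$tau_r
  ds  <- (1 / (1 + exp(-(v - p$s_vh)  / p$s_k))  - s)  / p$tau_s

  # calcium: ICaL influx + graded SR release (triggered above a small ICaL
  # threshold, zero at rest) - linear uptake/extrusion toward diastolic level
  trigger <- -ical - p$relThr
  if (trigger < 0) trigger <- 0
  jrel <- p$kRel * trigger * (casr - cai)
  jup  <- p$kUp  * (cai - p$CaiRest)
  jout <- p$kOut * (cai - p$CaiRest)
  dcai  <- -p$aCa * ical + jrel - jup - jout
  dcasr <- (jup - jrel) / p$vSR

  list(c(dv, dm, dhh, dhL, dd, df, dxr, dxs, dr, ds, dcai, dcasr),
       c(INa = ina, INaL = inal, ICaL = ical, IKr = ikr, IKs = iks,
         IK1 = ik1, Ito = ito, Istim = istim))
}

bundledParams <- function() {
  list(
    ENa = 65, EK = -91, ECa = 60, Vrest = -88,
    gNa = 11, m_vh = -40, m_k = 6, tau_m = 0.15,
    h_vh = -72, h_k = -6,
    tau_h_min = 0.8, tau_h_amp = 7, tau_h_vh = -50, tau_h_k = 6,
    gNaL = 0.08, mL_vh = -42, mL_k = 6, hL_vh = -87, hL_k = -7, tau_hL = 200,
    gCaL = 0.13, d_vh = -8, d_k = 6, tau_d = 1.5,
    f_vh = -24, f_k = -7, tau_f = 180,
    gKr = 0.10, xr_vh = -12, xr_k = 7, tau_xr = 300, rKr_vh = 10, rKr_k = 20,
    gKs = 0.05, xs_vh = -6, xs_k = 9, tau_xs = 320,
    gK1 = 0.6, k1_vh = -70, k1_k = 9,
    gto = 0.16, r_vh = 5, r_k = 9, tau_r = 3.5,
    s_vh = -35, s_k = -6, tau_s = 25,
    gLeak = 0.04,
    # calcium subsystem (mM, ms)
    CaiRest = 1e-4, CaSRInit = 1.2, vSR = 15,
    aCa = 4e-7, kRel = 1.5e-6, kUp = 4.5e-3, kOut = 1.5e-3, relThr = 0.01)
}

# Exact resting equilibrium: gates at their steady state for Vrest, Cai at
# CaiRest, and ELeak chosen so the total membrane current vanishes at Vrest.
bundledInitial <- function(p) {
  g <- bundledGates(p$Vrest, p)
  mult <- setNames(rep(1, 7), tdpChannels)
  cur <- bundledCurrents(p$Vrest, g, p$CaiRest, p, mult)
  state <- c(V = p$Vrest, g, Cai = p$CaiRest, CaSR = p$CaSRInit)
  ELeak <- p$Vrest + sum(cur) / p$gLeak
  list(state = state, ELeak = ELeak)
}

#' Construct an ionic model object
#'
#' An `IonicModel` is a plain list contract with elements:
#' `name`; `state0` (named initial state, a resting equilibrium); `rhs`
#' (`function(t, state, parms)` in deSolve form returning the derivative and
#' the named currents of [tdpChannels] as outputs); `parms0`
#' (`function(mult, stimAmp, stimEnd)` building the parameter list for one
#' integration segment); and `observables` (names of the voltage and calcium
#' state entries).
#'
#' @param name model name.
#' @param state0 named numeric initial state.
#' @param rhs deSolve-style right-hand side.
#' @param parms0 parameter-list builder, see above.
#' @param observables named list with entries `Vm` and `Cai` giving state names.
#' @return an object of class `IonicModel` (a list).
#' @export
makeIonicModel <- function(name, state0, rhs, parms0, observables) {
  structure(list(name = name, state0 = state0, rhs = rhs, parms0 = parms0,
                 observables = observables),
            class = "IonicModel")
}

#' The bundled reduced ventricular myocyte model
#'
#' Returns the packaged reduced Hodgkin-Huxley-style model exposing all seven
#' scalable channels, a human-ventricular-like action potential (resting about
#' -88 mV, APD90 within 150--400 ms at CL 2000 ms) and a decaying calcium
#' transient. Its initial state is an exact resting equilibrium: with all
#' multipliers 1 and no stimulus the right-hand side norm is below 1e-6.
#'
#' @return an `IonicModel` (see [makeIonicModel()]).
#' @export
bundledModel <- function() {
  p <- bundledParams()
  init <- bundledInitial(p)
  p$ELeak <- init$ELeak
  makeIonicModel(
    name = "torsadex-reduced-ventricular",
    state0 = init$state,
    rhs = bundledRHS,
    parms0 = function(mult, stimAmp, stimEnd)
      list(p = p, mult = mult, stimAmp = stimAmp, stimEnd = stimEnd),
    observables = list(Vm = "V", Cai = "Cai"))
}

#' Right-hand-side norm of a model at its initial state
#'
#' Diagnostic for the resting-equilibrium contract: the maximum absolute
#' derivative (model units per ms) with all multipliers 1 and no stimulus.
#'
#' @param model an `IonicModel`.
#' @return a non-negative scalar.
#' @export
restingResidual <- function(model) {
  mult <- setNames(rep(1, 7), tdpChannels)
  d <- model$rhs(1e9, model$state0, model$parms0(mult, 0, -1))[[1]]
  max(abs(d))
}
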