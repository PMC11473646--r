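triBeat <- function(cl = 400) {
  time <- seq(0, cl, by = 0.1)
  vm <- ifelse(time <= 1, -85 + 125 * time,
        ifelse(time <= 251, 40 - 0.5 * (time - 1), -85))
  cur <- matrix(0.1, length(time), 7, dimnames = list(NULL, tdpChannels))
  new("SimulationTrace", time = time, Vm = vm,
      Cai = 1e-4 + 5e-4 * exp(-time / 80) * (1 - exp(-time / 5)),
      currents = cur, beatStarts = 1L, cycleLength = cl)
}

test_that("durations from peak follow linear-triangle geometry", {
  b <- triBeat()
  expect_equal(durationAtFraction(b@time, b@Vm, 0.9), 225, tolerance = 0.1)
  expect_equal(durationAtFraction(b@time, b@Vm, 0.5), 125, tolerance = 0.1)
  # plateau at half amplitude never recovers to the 90% threshold
  vm <- b@Vm
  vm[b@time > 1] <- pmax(vm[b@time > 1], -22.5)
  expect_true(is.na(durationAtFraction(b@time, vm, 0.9)))
})

test_that("upstroke and repolarization rates are slopes, invariant to time shift", {
  b <- triBeat()
  r <- upstrokeAndRepolRates(b)
  expect_equal(r[["dVmdt_max"]], 125, tolerance = 1e-6)
  expect_equal(r[["dVmdt_repol"]], -0.5, tolerance = 1e-6)
  b2 <- b; b2@time <- b@time + 37.7
  expect_equal(upstrokeAndRepolRates(b2), r, tolerance = 1e-9)
})

test_that("resting potential and diastolic calcium read the expected segments", {
  b <- triBeat()
  v <- restingAndDiastolic(b)
  expect_equal(v[["Vm_resting"]], -85)
  expect_equal(v[["Ca_diastole"]], min(b@Cai))
  b2 <- b; b2@Cai <- b@Cai + 3e-4
  expect_equal(restingAndDiastolic(b2)[["Ca_diastole"]],
               v[["Ca_diastole"]] + 3e-4)
})

test_that("qNet integrates the six currents over one cycle length", {
  b <- triBeat(cl = 2000)
  b@currents[] <- 0.1
  expect_equal(qNet(b), 6 * 0.1 * 2000, tolerance = 1e-9)
  # currents summing to an odd function about mid-beat integrate to zero
  b@currents[] <- 0
  b@currents[, "IKr"] <- b@time - 1000
  expect_equal(qNet(b), 0, tolerance = 1e-6)
  short <- triBeat(cl = 400)
  short@cycleLength <- 2000
  expect_error(qNet(short), "shorter")
})

test_that("qNet trapezoid matches analytic polynomial integrals", {
  cl <- 2000
  time <- seq(0, cl, by = 0.1)
  cur <- matrix(0, length(time), 7, dimnames = list(NULL, tdpChannels))
  # quadratic test currents: analytic integral of a+bt+ct^2 over [0, cl]
  coef <- list(INaL = c(-0.1, 2e-4, 0), ICaL = c(-0.3, 1e-4, 1e-7),
               IKr = c(0.2, -1e-4, 2e-7), IKs = c(0.05, 0, 0),
               IK1 = c(0.15, 5e-5, 0), Ito = c(0.02, 0, -1e-8))
  analytic <- 0
  for (ch in names(coef)) {
    a <- coef[[ch]]
    cur[, ch] <- a[1] + a[2] * time + a[3] * time^2
    analytic <- analytic + a[1] * cl + a[2] * cl^2 / 2 + a[3] * cl^3 / 3
  }
  b <- new("SimulationTrace", time = time, Vm = rep(-85, length(time)),
           Cai = rep(1e-4, length(time)), currents = cur, beatStarts = 1L,
           cycleLength = cl)
  expect_equal(qNet(b), analytic, tolerance = 1e-9)
})

test_that("qInward is the sum of the two inward AUC ratios", {
  b <- triBeat(cl = 2000)
  b@currents[] <- 0
  b@currents[, "ICaL"] <- -0.5
  b@currents[, "INaL"] <- -0.2
  drug <- b
  drug@currents[, "ICaL"] <- -0.5 * 0.8
  drug@currents[, "INaL"] <- -0.2 * 0.5
  expect_identical(qInward(b, b), 2)
  expect_equal(qInward(drug, b), 1.3, tolerance = 1e-12)
  expect_equal(qInward(drug, b, halved = TRUE), 0.65, tolerance = 1e-12)
  full <- b; full@currents[, c("ICaL", "INaL")] <- 0
  expect_equal(qInward(full, b), 0)
  zero <- b; zero@currents[, "ICaL"] <- 0
  expect_error(qInward(b, zero), "degenerate control")
})

test_that("extractBiomarkers populates all twelve fields and the identities", {
  gw <- genWaveform()
  v <- extractBiomarkers(gw$trace, gw$trace)
  expect_named(v, tdpBiomarkers)
  expect_identical(v[["APD_tri"]], v[["APD90"]] - v[["APD50"]])
  expect_identical(v[["Ca_tri"]], v[["CaD90"]] - v[["CaD50"]])
  expect_identical(v[["qInward"]], 2)
  expect_gt(v[["dVmdt_max"]], 0)
  # a beat that never reaches 90% repolarization is dropped with a warning
  plateau <- gw$trace
  mid <- max(plateau@Vm) - 0.5 * (max(plateau@Vm) - plateau@Vm[1])
  post <- plateau@time > 1
  plateau@Vm[post] <- pmax(plateau@Vm[post], mid)
  expect_warning(out <- extractBiomarkers(plateau, gw$trace), "dropped")
  expect_null(out)
})

test_that("time-axis rescaling scales durations, rates and qNet coherently", {
  gw <- genWaveform(apd50 = 180, apd90 = 260, cad50 = 180, cad90 = 500)
  k <- 2
  sc <- gw$trace
  sc@time <- gw$trace@time * k
  sc@cycleLength <- gw$trace@cycleLength * k
  v1 <- extractBiomarkers(gw$trace, gw$trace)
  v2 <- extractBiomarkers(sc, sc)
  durs <- c("APD90", "APD50", "APD_tri", "CaD90", "CaD50", "Ca_tri")
  expect_equal(v2[durs], k * v1[durs], tolerance = 1e-6)
  rates <- c("dVmdt_max", "dVmdt_repol")
  expect_equal(v2[rates], v1[rates] / k, tolerance = 1e-6)
  expect_equal(v2[["qNet"]], k * v1[["qNet"]], tolerance = 1e-9)
})

test_that("simulated control beat yields a sane biomarker vector", {
  tr <- controlTrace()
  sel <- selectBeat(tr)
  beat <- traceBeat(tr, sel@selected)
  v <- extractBiomarkers(beat, beat)
  expect_gt(v[["APD90"]], 150); expect_lt(v[["APD90"]], 400)
  expect_lt(v[["Vm_resting"]], -80)
  expect_gt(v[["dVmdt_max"]], 100)
  expect_identical(v[["qInward"]], 2)
})
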