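test_that("bundled model starts at a resting equilibrium", {
  m <- bundledModel()
  expect_lt(restingResidual(m), 1e-6)
})

test_that("pacing bookkeeping: recorded span equals beats x cycle length", {
  tr <- controlTrace()
  pr <- testProtocol()
  expect_equal(nBeats(tr), pr$nRecorded)
  expect_equal(diff(range(tr@time)), pr$nRecorded * pr$cycleLength,
               tolerance = 1e-6)
  expect_true(all(diff(tr@time) > 0))
  # beat boundaries align with stimulus onsets (multiples of CL)
  expect_equal(tr@time[tr@beatStarts],
               (seq_len(nBeats(tr)) - 1) * pr$cycleLength)
})

test_that("pacing is deterministic and the all-ones profile is the control limit", {
  m <- bundledModel()
  pr <- pacingProtocol(nPrepace = 1, nDrugBeats = 2, nRecorded = 1)
  t1 <- runPacing(m, pr)
  t2 <- runPacing(m, pr, allOnes())
  expect_identical(t1@Vm, t2@Vm)
  expect_identical(t1@currents, t2@currents)
})

test_that("block input is validated", {
  m <- bundledModel()
  pr <- testProtocol()
  expect_error(runPacing(m, pr, c(IKr = 0.5)), "seven channels")
  bad <- allOnes(); bad["IKr"] <- 1.5
  expect_error(runPacing(m, pr, bad), "\\[0, 1\\]")
})

test_that("repolarization fractions recover triangular-beat geometry", {
  # triangular beat: rest -85, peak 40 at t = 1 ms, linear back at 251 ms
  time <- seq(0, 400, by = 0.1)
  vm <- ifelse(time <= 1, -85 + 125 * time,
        ifelse(time <= 251, 40 - 0.5 * (time - 1), -85))
  cur <- matrix(0, length(time), 7, dimnames = list(NULL, tdpChannels))
  beat <- new("SimulationTrace", time = time, Vm = vm,
              Cai = rep(1e-4, length(time)), currents = cur,
              beatStarts = 1L, cycleLength = 400)
  fr <- repolarizationFractions(beat)
  expect_equal(fr[["t90"]], 1 + 0.9 * 250, tolerance = 0.1)
  expect_equal(fr[["t50"]], 1 + 0.5 * 250, tolerance = 0.1)
  expect_equal(fr[["t30"]], 1 + 0.3 * 250, tolerance = 0.1)

  # affine rescaling of Vm leaves crossing times unchanged
  beat2 <- beat; beat2@Vm <- 0.5 * vm + 20
  expect_equal(repolarizationFractions(beat2), fr)

  # plateau at 50% amplitude never crosses 90%
  vm3 <- ifelse(time <= 1, -85 + 125 * time,
         ifelse(time <= 126, 40 - 0.5 * (time - 1), -22.5))
  beat3 <- beat; beat3@Vm <- vm3
  expect_true(is.na(repolarizationFractions(beat3)[["t90"]]))
})

test_that("beat selection follows the windowed max-repolarization-rate rule", {
  tr <- controlTrace()
  sel <- selectBeat(tr)
  expect_s4_class(sel, "BeatSelection")
  # identical steady-state beats: tie-break to the earliest beat
  expect_equal(sel@selected, 1L)
  expect_equal(sel@category[sel@selected], "full")

  # selection idempotence on the selected single beat
  single <- traceBeat(tr, sel@selected)
  expect_equal(selectBeat(single)@selected, 1L)

  # an injected late bump in the repolarization window wins the selection
  bump <- tr
  b2 <- tr@beatStarts[2]
  fr <- repolarizationFractions(traceBeat(tr, 2))
  at <- mean(c(fr[["t30"]], fr[["t90"]]))  # already on the absolute time axis
  bump@Vm <- tr@Vm + 15 * exp(-((tr@time - at) / 10)^2)
  expect_equal(selectBeat(bump)@selected, 2L)

  # a flatlined beat is excluded from the candidates
  flat <- tr
  idx <- seq(tr@beatStarts[1], tr@beatStarts[2] - 1L)
  flat@Vm[idx] <- flat@Vm[idx[1]]
  sel2 <- selectBeat(flat)
  expect_true(sel2@failed[1])
  expect_equal(sel2@selected, 2L)
  # all-failed traces raise the no-analyzable-AP error
  dead <- tr; dead@Vm[] <- -88
  expect_error(selectBeat(dead), "no analyzable AP")
})

test_that("IKr block prolongs APD90 in the bundled model", {
  m <- bundledModel()
  pr <- testProtocol()
  ctrl <- traceBeat(controlTrace(), 2)
  blk <- allOnes(); blk["IKr"] <- 0.5
  drug <- traceBeat(runPacing(m, pr, blk), 2)
  expect_gt(durationAtFraction(drug@time, drug@Vm, 0.9),
            durationAtFraction(ctrl@time, ctrl@Vm, 0.9))
})

test_that("zero ICaL collapses the calcium transient", {
  m <- bundledModel()
  blk <- allOnes(); blk["ICaL"] <- 0
  drug <- traceBeat(runPacing(m, testProtocol(), blk), 2)
  ctrl <- traceBeat(controlTrace(), 2)
  expect_lt(max(drug@Cai) - min(drug@Cai),
            0.5 * (max(ctrl@Cai) - min(ctrl@Cai)))
})

test_that("trace CSV export writes every grid point", {
  tr <- controlTrace()
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeTrace(tr, tmp)
  df <- read.csv(tmp)
  expect_equal(nrow(df), length(tr@time))
  expect_true(all(c("time_ms", "Vm_mV", "Cai", "IKr") %in% names(df)))
})
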