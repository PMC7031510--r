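# Single-compartment HVC_X simulator: equilibria, phenotype, protocols.

test_that("holding equilibrium is a fixed point of the integrated dynamics", {
  p <- refParams()
  eq <- holdingEquilibrium(p, -70)
  # simulate 1000 ms with the bias and no pulse: must stay within 0.1 mV
  tr <- simulateNeuron(p, stepProtocol(0, preMs = 0, stimMs = 0,
                                       postMs = 1000))
  expect_lt(max(abs(tr@voltageMv + 70)), 0.1)
  # a cell whose natural rest is the target needs ~zero holding current
  pl <- leakParams(gL = 5, EL = -70)
  expect_lt(abs(holdingEquilibrium(pl, -70)$holdingCurrentPa), 1e-6)
  # no-stimulus simulation from natural rest stays at rest
  vrest <- restingPotential(p)
  eq2 <- holdingEquilibrium(p, vrest)
  expect_lt(abs(eq2$holdingCurrentPa), 1e-6)
  tr2 <- simulateNeuron(p, stepProtocol(0, preMs = 0, stimMs = 0,
                                        postMs = 600, holdingMv = vrest))
  expect_lt(max(abs(tr2@voltageMv - vrest)), 0.5)
  # target outside the physiological window is refused
  expect_error(holdingEquilibrium(p, -40), "-90")
})

test_that("reference set fires an adapting spike train riding a plateau at +100 pA", {
  fv <- refFeatures()
  expect_identical(fv@nSpikes, REF_SPIKES)
  expect_equal(fv@isisMs[1], REF_FIRST_ISI, tolerance = 0.01)
  # accommodation: ISIs lengthen monotonically
  expect_true(all(diff(fv@isisMs) > 0))
  # the train rides on a depolarized plateau
  expect_gt(fv@plateauAmplitudeMv, 5)
  # holding current and input resistance in the reported biological range
  expect_lt(abs(holdingEquilibrium(refParams(), -70)$holdingCurrentPa), 35)
  rin <- inputResistance(list(refTrace(-10)))
  expect_gt(rin, 181 - 2 * 35)
  expect_lt(rin, 181 + 2 * 35)
})

test_that("h- and T-currents produce sag and rebound; removing them abolishes both", {
  tr <- refTrace(-140)
  expect_gt(sagAmplitude(tr), 2)
  expect_gte(refFeatures()@reboundSpikes, 1)
  p0 <- withConductances(refParams(), c(gh = 0, gCaT = 0))
  t0 <- simulateNeuron(p0, stepProtocol(-140))
  expect_lt(sagAmplitude(t0), 0.2)
  f0 <- extractFeatures(simulateNeuron(p0, stepProtocol(100)), t0)
  expect_identical(f0@reboundSpikes, 0L)
  # g_h alone controls the sag
  ph <- withConductances(refParams(), c(gh = 0))
  expect_lt(sagAmplitude(simulateNeuron(ph, stepProtocol(-140))), 0.2)
})

test_that("spike count grows with depolarizing amplitude and falls with g_SK", {
  counts <- vapply(seq(40, 200, by = 40), function(a)
    nrow(detectSpikes(refTrace(a), window = c(200, 400))), numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[5], counts[1])
  sk_counts <- vapply(c(0, 2, 4, 8, 12), function(g) {
    pp <- withConductances(refParams(), c(gSK = g))
    nrow(detectSpikes(simulateNeuron(pp, stepProtocol(100)),
                      window = c(200, 400)))
  }, numeric(1))
  expect_true(all(diff(sk_counts) <= 0))
})

test_that("integration converges in dt", {
  p <- refParams()
  # sample-wise convergence at fine step: halving dt moves no sample > 0.1 mV
  t1 <- simulateNeuron(p, stepProtocol(100, dtMs = 0.005))
  t2 <- simulateNeuron(p, stepProtocol(100, dtMs = 0.0025))
  expect_lt(max(abs(t1@voltageMv -
                    t2@voltageMv[seq(1, length(t2@voltageMv), 2)])), 0.1)
  # feature-level convergence at the working step
  f1 <- extractFeatures(refTrace(100), refTrace(-140))
  f2 <- extractFeatures(simulateNeuron(p, stepProtocol(100, dtMs = 0.01)),
                        simulateNeuron(p, stepProtocol(-140, dtMs = 0.01)))
  expect_identical(f1@nSpikes, f2@nSpikes)
  expect_lt(max(abs(f1@spikeTimesMs - f2@spikeTimesMs)), 0.5)
})

test_that("divergent parameter sets fail with an explicit error naming the conductances", {
  # a pathological set: huge Na, no K/leak to restrain it, coarse dt
  p <- withConductances(refParams(),
                        c(gNa = 100000, gK = 0, gSK = 0, gh = 0, gCaT = 0,
                          gL = 0.1))
  expect_error(simulateNeuron(p, stepProtocol(200, dtMs = 0.1)),
               "diverged.*gNa", ignore.case = TRUE)
})

test_that("canonical protocol family matches the published stimulation set", {
  prs <- canonicalProtocols()
  expect_length(prs, 12L)
  amps <- vapply(prs, function(x) x@amplitude, numeric(1))
  expect_setequal(unique(amps),
                  c(seq(40, 200, 40), seq(-40, -200, -40), 100, -140))
  expect_true(all(seq(40, 200, 40) %in% amps))
  expect_true(all(seq(-40, -200, -40) %in% amps))
  # the canonical fitting pair is present explicitly
  expect_equal(prs[["canonical+100"]]@amplitude, 100)
  expect_equal(prs[["canonical-140"]]@amplitude, -140)
  durs <- vapply(prs, function(x) c(x@preMs, x@stimMs, x@postMs), numeric(3))
  expect_true(all(durs == 200))
})

test_that("chaotic stimulus is seed-deterministic, bounded and seed-decorrelated", {
  s1 <- chaoticStimulus(5, scale = 150, durationMs = 500)
  s2 <- chaoticStimulus(5, scale = 150, durationMs = 500)
  expect_identical(s1@waveform, s2@waveform)
  expect_lte(max(abs(s1@waveform)), 150)
  expect_lt(abs(mean(s1@waveform)), 1e-9)
  cors <- vapply(1:20, function(k) {
    a <- chaoticStimulus(2 * k, 100, 300)@waveform
    b <- chaoticStimulus(2 * k + 1, 100, 300)@waveform
    abs(cor(a, b))
  }, numeric(1))
  expect_true(mean(cors < 0.5) >= 0.9)
  # it actually drives the neuron
  tr <- simulateNeuron(refParams(), chaoticStimulus(1, 150, 400))
  expect_gt(diff(range(tr@voltageMv)), 10)
})

test_that("parameter validity catches unphysical sets", {
  p <- refParams()
  expect_error(withConductances(p, c(gNa = -5)), "0")
  bad <- p; bad@reversals[["EK"]] <- 10
  expect_error(validObject(bad), "ENa > 0 > EK")
})
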