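# Generators: osmometer forward model, fluorescence transduction, Arrhenius
# and decay series, survival counts.

test_that("volume relaxation reaches the closed-form osmotic equilibrium", {
  cell <- simCellSpec(Pf = 4.94e-3, osmIn0 = 1.4, osmOut = 1.75)
  v <- simulateVolumeRelaxation(cell, seq(0, 20, by = 0.01))
  expect_equal(tail(v, 1), 1.4 / 1.75, tolerance = 1e-5)
  expect_true(all(diff(v) <= 1e-12))           # monotone non-increasing
  expect_true(all(v > 1.4 / 1.75 - 1e-6))      # bounded by equilibrium

  # with a non-osmotic fraction the plateau shifts accordingly
  cellB <- simCellSpec(Pf = 4.94e-3, nonosmoticFraction = 0.3)
  vB <- simulateVolumeRelaxation(cellB, seq(0, 20, by = 0.01))
  expect_equal(tail(vB, 1), 0.3 + 0.7 * 1.4 / 1.75, tolerance = 1e-5)
})

test_that("zero permeability gives a flat volume trace", {
  v <- simulateVolumeRelaxation(simCellSpec(Pf = 0), seq(0, 1, 0.01))
  expect_equal(v, rep(1, 101))
})

test_that("time validation rejects malformed inputs", {
  cell <- simCellSpec(Pf = 1e-3)
  expect_error(simulateVolumeRelaxation(cell, c(0, 0.2, 0.1)),
               "strictly increasing")
  expect_error(simCellSpec(Pf = 1e-3, osmOut = -1), "osmOut")
})

test_that("osmolyte amount is conserved along simulated trajectories", {
  # reconstruct the internal osmolarity implied by the flux balance from a
  # numerical derivative of v; osm_in (v - vb) must stay at osm_in0 (1 - vb)
  cell <- simCellSpec(Pf = 4.94e-3, nonosmoticFraction = 0.1)
  const <- physicalConstants()
  times <- seq(0, 2, by = 1e-3)
  v <- simulateVolumeRelaxation(cell, times)
  rate <- cell@Pf * (6 / (cell@diameter * 1e-4)) * const@Vw * 1e-3
  mid <- 2:(length(v) - 1)
  dvdt <- (v[mid + 1] - v[mid - 1]) / (2e-3)
  osmIn <- cell@osmOut + dvdt / rate
  amount <- osmIn * (v[mid] - cell@nonosmoticFraction)
  expected <- cell@osmIn0 * (1 - cell@nonosmoticFraction)
  expect_lt(max(abs(amount / expected - 1)), 1e-6)
})

test_that("small-shock simulation matches the linearised exponential rate", {
  cell <- simCellSpec(Pf = 4.94e-3, osmIn0 = 1.4, osmOut = 1.4 * 1.01)
  times <- seq(0, 30, by = 0.01)
  v <- simulateVolumeRelaxation(cell, times)
  fit <- fitSingleExponential(makeShrinkageTrace(times, v))
  kLin <- linearShrinkageRate(4.94e-3, 5, 1.4 * 1.01)
  expect_equal(fit@k, kLin, tolerance = 0.01)
})

test_that("fluorescence transduction is affine, dead-time-trimmed, seeded", {
  cell <- simCellSpec(Pf = 4.94e-3)
  times <- seq(0, 2, by = 1e-3)
  v <- simulateVolumeRelaxation(cell, times)

  # identity transduction
  ins0 <- instrumentSpec(deadTime = 0, noiseSd = 0)
  tr0 <- volumeToFluorescence(v, times, ins0, cell = cell)
  expect_equal(tr0@fluorescence, v)

  # dead-time samples dropped
  ins <- instrumentSpec(deadTime = 0.002, noiseSd = 0)
  tr <- volumeToFluorescence(v, times, ins, cell = cell)
  expect_true(all(tr@times >= 0.002))
  expect_length(tr@times, sum(times >= 0.002))

  # bit-identical under a fixed seed
  insN <- instrumentSpec(noiseSd = 0.005, seed = 11)
  trA <- volumeToFluorescence(v, times, insN, cell = cell)
  trB <- volumeToFluorescence(v, times, insN, cell = cell)
  expect_identical(trA@fluorescence, trB@fluorescence)

  # ground truth travels with the trace
  expect_equal(groundTruth(trA)$PfTrue, 4.94e-3)
  expect_error(volumeToFluorescence(v, times,
                                    instrumentSpec(fluorGain = 0)),
               "degenerate")
})

test_that("generated noise has the advertised standard deviation", {
  v <- rep(1, 1000)
  times <- seq(0, 0.999, by = 1e-3)
  ins <- instrumentSpec(deadTime = 0, duration = 1, noiseSd = 0.005,
                        seed = 4)
  tr <- volumeToFluorescence(v, times, ins)
  expect_gte(sd(tr@fluorescence - 1), 0.004)
  expect_lte(sd(tr@fluorescence - 1), 0.006)
})

test_that("Arrhenius generator follows the closed form", {
  const <- physicalConstants()
  arr <- generateArrheniusSeries(6.52, 4.94e-3, 296.15,
                                 c(282.15, 307.15))
  slope <- diff(log(arr$Pf)) / diff(1 / arr$temperatureK)
  expect_equal(slope, -6.52 / 1.9872e-3, tolerance = 1e-10)
  expect_equal(slope, -3281.0, tolerance = 1e-4)

  # Ea = 0 leaves Pf constant; at T = TRef, Pf = PfRef exactly
  flat <- generateArrheniusSeries(0, 2e-3, 296.15, c(280, 290, 300))
  expect_equal(flat$Pf, rep(2e-3, 3))
  atRef <- generateArrheniusSeries(6.52, 2e-3, 296.15, 296.15)
  expect_equal(atRef$Pf, 2e-3)
  expect_true(attr(atRef, "insufficientPoints"))
})

test_that("decay generator matches closed forms in both readout modes", {
  tr <- generateDecayTrace(50, 2e-3, duration = 500, sampleRate = 0.002)
  expect_equal(tail(tr@values, 1), 50 * exp(-1), tolerance = 1e-9)
  expect_equal(tail(tr@values, 1), 18.394, tolerance = 1e-4)

  o2 <- generateDecayTrace(50, 2e-3, duration = 500, sampleRate = 0.002,
                           mode = "o2")
  expect_equal(tail(o2@values, 1), 9.197, tolerance = 1e-4)

  flat <- generateDecayTrace(50, 0, duration = 10, sampleRate = 1)
  expect_equal(flat@values, rep(50, 11))

  # clipping floor and determinism
  noisy <- generateDecayTrace(1, 0.05, duration = 200, sampleRate = 1,
                              noiseSd = 0.3, seed = 9)
  expect_true(all(noisy@values >= 1e-3))
  expect_gt(noisy@nClipped, 0L)
  again <- generateDecayTrace(1, 0.05, duration = 200, sampleRate = 1,
                              noiseSd = 0.3, seed = 9)
  expect_identical(noisy@values, again@values)
})

test_that("survival count generator honours its curve and dispersion", {
  flat <- generateSurvivalCounts(250, data.frame(time = c(10, 20),
                                                 fraction = c(1, 1)),
                                 dispersion = "none")
  expect_equal(flat$count, rep(250, 3))

  half <- generateSurvivalCounts(250, data.frame(time = 30,
                                                 fraction = 0.5),
                                 dispersion = "none")
  expect_equal(half$count[half$time == 30], 125)

  expect_error(generateSurvivalCounts(250,
                                      data.frame(time = 1, fraction = 1.2)),
               "fractions")

  # Poisson dispersion: mean recovered fraction within 2% over 500 seeds
  rec <- vapply(1:500, function(s) {
    cts <- generateSurvivalCounts(250, data.frame(time = 30,
                                                  fraction = 0.5),
                                  dispersion = "poisson", seed = s)
    cts$count[cts$time == 30] / 250
  }, numeric(1))
  expect_equal(mean(rec), 0.5, tolerance = 0.02)
})
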