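test_that("makeRTTruth is deterministic and couples tracks through kappa", {
  gb <- deskBins()
  t1 <- makeRTTruth(gb, seed = 3)
  t2 <- makeRTTruth(gb, seed = 3)
  expect_identical(rtProgram(t1), rtProgram(t2))
  expect_identical(ladStates(t1), ladStates(t2))
  expect_identical(as.data.frame(originSites(t1)), as.data.frame(originSites(t2)))

  # kappa = 0: tracks independent of the timing program
  t0 <- makeRTTruth(gb, coupling = 0, seed = 5)
  expect_lt(abs(cor(rtProgram(t0), ladStates(t0))), 0.1)
  expect_lt(abs(cor(rtProgram(t0), compartmentScore(t0))), 0.15)
  oc0 <- binTrack(originSites(t0), genomeBins(t0), "count")
  expect_lt(abs(cor(rtProgram(t0), oc0)), 0.1)

  # kappa = 3: late bins lamina-associated, origin-poor, B-compartment
  t3 <- makeRTTruth(gb, coupling = 3, seed = 5)
  expect_gt(cor(rtProgram(t3), ladStates(t3)), 0.3)
  expect_lt(cor(rtProgram(t3), compartmentScore(t3)), -0.3)
  oc3 <- binTrack(originSites(t3), genomeBins(t3), "count")
  expect_lt(cor(rtProgram(t3), oc3), -0.1)

  expect_true(all(rtProgram(t3) >= 0 & rtProgram(t3) <= 1))
  expect_error(makeRTTruth(gb, coupling = -1), "coupling")
})

test_that("simulateCells reproduces the copy-doubling readout and truth", {
  truth <- makeRTTruth(deskBins(), seed = 3)

  # noise-free high depth: replicated bins carry twice the signal
  clean <- simulateCells(truth, nG1 = 0, nS = 4, meanReadsPerCell = 5e6,
                         nbDispersion = Inf, ampNoiseSd = 0, gcCoeff = 0,
                         flipRate = 0, seed = 9)
  cnt <- assay(clean, "counts")
  st <- trueStates(clean)
  for (j in 1:4) {
    ratio <- mean(cnt[st[, j] == 1L, j]) / mean(cnt[st[, j] == 0L, j])
    expect_equal(ratio, 2, tolerance = 0.025)
  }

  # all-G1 cohort: all-zero truth states
  g1only <- simulateCells(truth, nG1 = 5, nS = 0, seed = 2)
  expect_true(all(trueStates(g1only) == 0L))
  expect_true(all(cellPhase(g1only) == "G1"))

  # determinism
  a <- simulateCells(truth, nG1 = 2, nS = 3, seed = 4)
  b <- simulateCells(truth, nG1 = 2, nS = 3, seed = 4)
  expect_identical(assay(a, "counts"), assay(b, "counts"))

  # read-depth conservation within 2%
  sim <- studySim()
  expect_equal(mean(colSums(assay(sim, "counts"))), 1e6, tolerance = 0.02)

  # monotonicity: pre-flip replicated fraction is non-decreasing in f
  noflip <- simulateCells(truth, nG1 = 0, nS = 40, flipRate = 0, seed = 8)
  frac <- colMeans(trueStates(noflip))
  expect_true(all(diff(frac[order(sFraction(noflip))]) >= 0))

  expect_error(simulateCells(truth, flipRate = 0.5), "flipRate")
  expect_error(simulateCells(truth, nG1 = 0, nS = 0), "nG1")
  expect_error(simulateCells(truth, fRange = c(0.9, 0.1)), "fRange")
})

test_that("injectCNEvent rescales counts and records the event", {
  truth <- makeRTTruth(deskBins(), seed = 3)
  sim <- simulateCells(truth, nG1 = 3, nS = 0, meanReadsPerCell = 4e6,
                       nbDispersion = Inf, ampNoiseSd = 0, seed = 6)
  region <- GRanges("chr1", IRanges(10000001, 20000000))
  inBins <- 101:200

  # full deletion zeroes the region
  del <- injectCNEvent(sim, "cell001", region, deltaCn = -2, seed = 1)
  expect_true(all(assay(del, "counts")[inBins, "cell001"] == 0L))

  # +2 doubles the region at high depth
  amp <- injectCNEvent(sim, "cell002", region, deltaCn = 2, seed = 1)
  ratio <- mean(assay(amp, "counts")[inBins, "cell002"]) /
    mean(assay(sim, "counts")[inBins, "cell002"])
  expect_equal(ratio, 2, tolerance = 0.02)

  # whole-chromosome form and event bookkeeping
  wc <- injectCNEvent(amp, "cell003", "chr2", deltaCn = 1, seed = 1)
  ev <- cnEvents(wc)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$end[2L], 1e8)

  expect_error(injectCNEvent(sim, "nope", region, 2), "unknown cell")
  expect_error(injectCNEvent(sim, "cell001", region, -3), "baselineCn")
  expect_error(injectCNEvent(sim, "cell001", region, 0), "non-zero")
  expect_error(
    injectCNEvent(sim, "cell001", GRanges("chr1", IRanges(1, 2e8)), 1),
    "region"
  )
})
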