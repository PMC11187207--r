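test_that("binarizeCell separates clean 1x/2x profiles exactly", {
  truth <- makeRTTruth(deskBins(), seed = 7)
  s <- as.integer(rtProgram(truth) <= 0.5)
  res <- binarizeCell(1 + s)
  expect_true(res$informative)
  expect_identical(res$states, s)
  expect_equal(res$percentReplicated, mean(s))

  # constant input: zero separation, non-informative
  flat <- binarizeCell(rep(1, 500))
  expect_false(flat$informative)
  expect_true(all(is.na(flat$states)))

  expect_error(binarizeCell(rep(1, 50)), "insufficient")
})

test_that("two-means clustering equals exhaustive within-cluster SSE minimization", {
  withinSSE <- function(v, thr) {
    lo <- v[v <= thr]
    hi <- v[v > thr]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }
  set.seed(99)
  for (i in 1:20) {
    n <- sample(120:200, 1)
    v <- c(rnorm(n %/% 2, 1, 0.15), rnorm(n - n %/% 2, 2, 0.15))
    res <- binarizeCell(v, smoothWindow = 1L, minBins = 100L)
    # exhaustive threshold scan over all midpoints between sorted values
    sv <- sort(v)
    cand <- (sv[-1] + sv[-n]) / 2
    best <- cand[which.min(vapply(cand, withinSSE, numeric(1), v = v))]
    expect_identical(res$states, as.integer(v > best))
  }
})

test_that("aggregateProfile counts informative states per bin", {
  gb <- partitionGenome(c(chrA = 3e5), 1e5)
  st <- cbind(c(1L, 0L, NA), c(1L, 0L, 0L), c(0L, 0L, 1L))
  agg <- aggregateProfile(st, gb)
  expect_equal(rtFraction(agg), c(2 / 3, 0, 1 / 2))
  expect_equal(nInformative(agg), c(3L, 3L, 2L))

  single <- aggregateProfile(cbind(c(1L, 0L, 1L)), gb)
  expect_equal(rtFraction(single), c(1, 0, 1))

  expect_error(aggregateProfile(matrix(integer(), nrow = 3, ncol = 0), gb),
               "degenerate")
})

test_that("early/late classes use strict 50% inequalities and conserve bins", {
  expect_equal(as.character(classifyEarlyLate(c(0.6, 0.4, 0.5))),
               c("early", "late", "boundary"))

  sim <- studySim()
  qc <- qcCells(sim, thresholds = "calibrate")
  sCells <- qc$qc$cell[qc$qc$phase == "S"]
  binary <- cached("studyBinary",
                   binarizeCells(qc$copyRatio[, sCells, drop = FALSE],
                                 bins = genomeBins(sim)))
  agg <- aggregateProfile(binary, genomeBins(sim))
  cls <- rtClass(agg)
  unmasked <- !binMask(genomeBins(sim))
  counts <- table(cls[unmasked])
  expect_equal(sum(counts), sum(unmasked & !is.na(rtFraction(agg))))
  expect_equal(sum(counts), sum(unmasked))  # every unmasked bin classified

  # relabelling cells leaves the aggregate unchanged
  st <- rtStates(binary)[, isInformative(binary)]
  perm <- sample(ncol(st))
  expect_equal(rtFraction(aggregateProfile(st[, perm], genomeBins(sim))),
               rtFraction(agg))
})

test_that("correlateProfiles matches expectations on aligned profiles", {
  a <- runif(100)
  expect_equal(correlateProfiles(a, a)$r, 1)
  expect_equal(correlateProfiles(a, 1 - a)$r, -1)

  # independent timing programs decorrelate
  t1 <- rtProgram(makeRTTruth(deskBins(), coupling = 0, seed = 31))
  t2 <- rtProgram(makeRTTruth(deskBins(), coupling = 0, seed = 32))
  expect_lt(abs(correlateProfiles(t1, t2)$r), 0.1)

  expect_error(correlateProfiles(a[1:5], a[1:5]), "insufficient")
  expect_error(correlateProfiles(rep(1, 100), a), "undefined correlation")
})

test_that("orderCells sorts stably by percent replicated", {
  st <- matrix(c(1L, 1L, 1L, 0L,   0L, 0L, 1L, 0L,   1L, 1L, 0L, 0L),
               nrow = 4)
  colnames(st) <- c("cell1", "cell2", "cell3")
  b <- new("BinaryRT", states = st,
           percentReplicated = c(0.8, 0.2, 0.5),
           informative = rep(TRUE, 3), separation = rep(1, 3),
           threshold = rep(1.5, 3))
  ord <- orderCells(b)
  expect_equal(ord$permutation, c(2L, 3L, 1L))
  expect_equal(colnames(rtStates(ord$binary)), c("cell2", "cell3", "cell1"))

  # ties break by cell id, preserving a stable order
  bt <- new("BinaryRT", states = st,
            percentReplicated = c(0.5, 0.5, 0.5),
            informative = rep(TRUE, 3), separation = rep(1, 3),
            threshold = rep(1.5, 3))
  expect_equal(orderCells(bt)$permutation, 1:3)

  empty <- new("BinaryRT", states = matrix(integer(), nrow = 4, ncol = 0),
               percentReplicated = numeric(), informative = logical(),
               separation = numeric(), threshold = numeric())
  expect_equal(length(orderCells(empty)$permutation), 0L)
})
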