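test_that("segmentCell recovers clean changepoints exactly", {
  gb <- partitionGenome(c(chr1 = 1e7), 1e5)  # 100 bins
  x <- c(rep(1, 40), rep(2, 60))
  seg <- cnSegments(segmentCell(x, gb))
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$lastBin[1L], 40L)
  expect_equal(seg$meanRatio, c(1, 2))

  # agrees with exhaustive single-changepoint search on the clean input
  sse1 <- vapply(5:95, function(s) {
    sum((x[1:s] - mean(x[1:s]))^2) + sum((x[-(1:s)] - mean(x[-(1:s)]))^2)
  }, numeric(1))
  expect_equal((5:95)[which.min(sse1)], 40L)

  expect_equal(nrow(cnSegments(segmentCell(rep(1.3, 100), gb))), 1L)

  # minimum-length constraint: two changes 10 bins apart cannot both be
  # resolved with minSegBins 20 — every reported segment is >= 20 bins, so
  # reported boundaries are >= 20 bins apart
  y <- c(rep(1, 45), rep(2, 10), rep(1, 45))
  segs <- cnSegments(segmentCell(y, gb, minSegBins = 20L))
  expect_true(all(segs$nBins >= 20L))
  expect_lte(nrow(segs), 3L)

  expect_warning(segmentCell(c(rep(1, 6), rep(NA, 94)), gb, minSegBins = 5L),
                 "single segment")
})

test_that("callCopyNumber scales by the length-weighted median", {
  gb <- partitionGenome(c(chr1 = 1e7), 1e5)
  seg <- callCopyNumber(segmentCell(rep(1, 100), gb))
  expect_true(all(cnSegments(seg)$cnCont == 2))
  expect_true(all(cnSegments(seg)$cnInt == 2L))

  x <- c(rep(1, 80), rep(2, 20))
  cn <- cnSegments(callCopyNumber(segmentCell(x, gb)))
  expect_equal(cn$cnCont, c(2, 4))
  y <- c(rep(1, 80), rep(0.5, 20))
  cn2 <- cnSegments(callCopyNumber(segmentCell(y, gb)))
  expect_equal(cn2$cnCont, c(2, 1))

  zeroSeg <- segmentCell(rep(0, 100), gb)
  expect_error(callCopyNumber(zeroSeg), "degenerate")
})

test_that("annotateBreakpoints applies the strict |delta CN| > 1 rule", {
  mkseg <- function(cns, nb = 50L) {
    k <- length(cns)
    segs <- data.frame(
      chrom = "chr1",
      start = (seq_len(k) - 1L) * nb * 1e5 + 1,
      end = seq_len(k) * nb * 1e5,
      firstBin = (seq_len(k) - 1L) * nb + 1L,
      lastBin = seq_len(k) * nb,
      nBins = nb, meanRatio = cns / 2, cnCont = cns,
      cnInt = as.integer(floor(cns + 0.5)), stringsAsFactors = FALSE
    )
    new("SegmentedCN", cellId = "c1", segments = segs)
  }
  # 2 -> 4: break with delta +2 at the shared boundary
  br <- annotateBreakpoints(mkseg(c(2, 4)))
  expect_equal(nrow(br), 1L)
  expect_equal(br$deltaCn, 2)
  expect_equal(br$position, 50 * 1e5)

  # delta exactly 1 never qualifies (strict inequality)
  expect_equal(nrow(annotateBreakpoints(mkseg(c(2, 3)))), 0L)
  expect_equal(nrow(annotateBreakpoints(mkseg(c(2, 3, 2, 3, 2)))), 0L)

  # 2 -> 0.5 qualifies with delta -1.5
  expect_equal(annotateBreakpoints(mkseg(c(2, 0.5)))$deltaCn, -1.5)

  # chromosome ends never emit; a single segment yields nothing
  expect_equal(nrow(annotateBreakpoints(mkseg(4))), 0L)

  expect_error(annotateBreakpoints(segmentCell(rep(1, 100),
                                               partitionGenome(c(chr1 = 1e7), 1e5))),
               "callCopyNumber")
})

test_that("segments partition unmasked bins disjointly", {
  co <- eventCohort()
  sim <- co$sim
  bins <- genomeBins(sim)
  ref <- buildG1Reference(assay(sim, "counts"), bins, method = "median")
  x <- normalizeToReference(assay(sim, "counts")[, 1], ref, bins)
  seg <- cnSegments(segmentCell(x, bins, cellId = "cell001"))
  covered <- unlist(mapply(seq, seg$firstBin, seg$lastBin))
  expect_equal(sort(covered), which(!binMask(bins) & !is.na(x)))
  expect_equal(anyDuplicated(covered), 0L)
})

test_that("summarizeKaryotypes calls whole-chromosome and segmental changes", {
  # 4 chromosomes: a single whole-chromosome loss leaves a euploid majority
  # of the genome to anchor the copy-number scale
  gb4 <- partitionGenome(setNames(rep(5e7, 4), paste0("chr", 1:4)), 1e5)
  truth <- makeRTTruth(gb4, seed = 7)
  sim <- simulateCells(truth, nG1 = 20, nS = 0, flipRate = 0, seed = 15)
  bins <- genomeBins(sim)
  # 10 cells get a whole-chromosome loss on chr2
  for (i in 1:10) {
    sim <- injectCNEvent(sim, sprintf("cell%03d", i), "chr2", -1L, seed = i)
  }
  # reference from the event-free cells (with 50% prevalence even a median
  # cohort reference would absorb the shared loss)
  ref <- buildG1Reference(assay(sim, "counts"), bins,
                          cells = sprintf("cell%03d", 11:20))
  x <- normalizeToReference(assay(sim, "counts"), ref, bins)
  segs <- lapply(colnames(x), function(id) {
    callCopyNumber(segmentCell(x[, id], bins, cellId = id))
  })
  karyo <- summarizeKaryotypes(segs, bins)
  perChrom <- karyo$perChromosome
  expect_equal(sum(perChrom$call == "loss" & perChrom$chrom == "chr2"), 10L)
  expect_equal(karyo$aneuploidyFraction, 0.5)
  expect_equal(sum(karyo$counts), 80L)

  # an event-free cohort is euploid throughout
  clean <- simulateCells(truth, nG1 = 6, nS = 0, flipRate = 0, seed = 16)
  refC <- buildG1Reference(assay(clean, "counts"), bins)
  xc <- normalizeToReference(assay(clean, "counts"), refC, bins)
  segsC <- lapply(colnames(xc), function(id) {
    callCopyNumber(segmentCell(xc[, id], bins, cellId = id))
  })
  karyoC <- summarizeKaryotypes(segsC, bins)
  expect_equal(karyoC$aneuploidyFraction, 0)
  expect_true(all(karyoC$perChromosome$call == "euploid"))
})
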