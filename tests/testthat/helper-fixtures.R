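# Shared fixtures, all generated in code.

# Desk-scale genome used throughout: 2 chromosomes x 100 Mb, 100 kb bins.
deskBins <- function() {
  partitionGenome(c(chr1 = 1e8, chr2 = 1e8), binSize = 1e5)
}

# Tiny genome for interval arithmetic tests: 1 Mb + 0.55 Mb, 100 kb bins
# (the second chromosome ends in a short, masked bin).
tinyBins <- function() {
  partitionGenome(c(chrA = 1e6, chrB = 5.5e5), binSize = 1e5)
}

# Cache expensive simulations across test files within one run.
.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, expr, envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

# The headline study conditions: 30 G1 + 150 S cells, 1M reads, NB
# dispersion 10, amplification noise 0.1, flip rate as requested, seed 7.
studySim <- function(flipRate = 0.02) {
  key <- paste0("studySim_", flipRate)
  cached(key, {
    truth <- cached("studyTruth", makeRTTruth(deskBins(), seed = 7))
    simulateCells(truth, flipRate = flipRate, seed = 7)
  })
}

# Cohort with one injected segmental |dCN| = 2 event per cell, placed at
# least 10 bins from chromosome ends (an edge closer to the end than
# minSegBins cannot be bounded by any minimum-length segmenter).
eventCohort <- function(nCells = 50L, deltas = c(-2L, 2L), seed = 11L) {
  cached(paste0("eventCohort_", nCells, "_", seed), {
    truth <- cached("studyTruth", makeRTTruth(deskBins(), seed = 7))
    sim <- simulateCells(truth, nG1 = nCells, nS = 0L, flipRate = 0,
                         seed = seed)
    bins <- genomeBins(sim)
    nPerChrom <- nBins(bins) / 2L
    events <- vector("list", nCells)
    set.seed(seed + 90L)
    for (i in seq_len(nCells)) {
      id <- colnames(sim)[i]
      chr <- sample(chromNames(bins), 1L)
      nb <- sample(20:60, 1L)
      startBin <- sample(11:(nPerChrom - 10L - nb), 1L)
      st <- (startBin - 1L) * binSize(bins) + 1L
      en <- (startBin - 1L + nb) * binSize(bins)
      delta <- sample(deltas, 1L)
      sim <- injectCNEvent(sim, id,
                           GenomicRanges::GRanges(chr, IRanges::IRanges(st, en)),
                           delta)
      events[[i]] <- data.frame(cell = id, chrom = chr, start = st, end = en,
                                deltaCn = delta, stringsAsFactors = FALSE)
    }
    list(sim = sim, events = do.call(rbind, events))
  })
}
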