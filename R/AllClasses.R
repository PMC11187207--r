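#' GenomeBins: fixed-width tiling of a genome
#'
#' The coordinate backbone shared by every analysis stage: an ordered,
#' contiguous tiling of each chromosome into `binSize`-bp bins (the last bin
#' of a chromosome may be shorter), carrying an optional per-bin GC fraction
#' and a boolean analysis mask (`TRUE` = excluded).
#'
#' @slot bins A [GenomicRanges::GRanges] with one range per bin, in genome
#'   order, with metadata columns `gc` (numeric in \[0,1\] or `NA`) and
#'   `mask` (logical).
#' @slot binSize Integer bin width in bp.
#'
#' @seealso [partitionGenome()]
#' @name GenomeBins-class
#' @aliases GenomeBins
#' @exportClass GenomeBins
setClass("GenomeBins", slots = c(bins = "GRanges", binSize = "integer"))

setValidity("GenomeBins", function(object) {
  gr <- object@bins
  msgs <- character()
  if (length(object@binSize) != 1L || is.na(object@binSize) ||
      object@binSize <= 0L) {
    msgs <- c(msgs, "binSize must be a single positive integer")
  }
  if (!all(c("gc", "mask") %in% names(mcols(gr)))) {
    msgs <- c(msgs, "bins must carry 'gc' and 'mask' metadata columns")
  } else {
    gc <- mcols(gr)$gc
    if (!is.numeric(gc) || any(gc < 0 | gc > 1, na.rm = TRUE)) {
      msgs <- c(msgs, "gc must be numeric in [0,1] (NA allowed)")
    }
    if (!is.logical(mcols(gr)$mask) || anyNA(mcols(gr)$mask)) {
      msgs <- c(msgs, "mask must be logical without NA")
    }
  }
  # contiguous tiling, full-width bins except possibly the last per chromosome
  if (length(gr) > 0L && length(msgs) == 0L) {
    sl <- seqlengths(gr)
    for (chr in seqlevels(gr)) {
      b <- gr[seqnames(gr) == chr]
      if (length(b) == 0L) next
      if (start(b)[1L] != 1L ||
          any(start(b)[-1L] != end(b)[-length(b)] + 1L)) {
        msgs <- c(msgs, sprintf("bins on %s are not contiguous from 1", chr))
      }
      if (length(b) > 1L && any(width(b)[-length(b)] != object@binSize)) {
        msgs <- c(msgs, sprintf("interior bins on %s are not binSize wide", chr))
      }
      if (!is.na(sl[chr]) && sum(as.numeric(width(b))) != sl[chr]) {
        msgs <- c(msgs, sprintf("bins on %s do not sum to chromosome length", chr))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' RTTruth: a known single-cell replication-timing program
#'
#' Ground truth produced by the synthetic-data generator: a smooth per-bin
#' replication schedule `t` (0 = earliest, 1 = latest) together with feature
#' tracks coupled to it with strength `coupling` — lamina-associated domains
#' (probability increasing in t), an A/B-compartment-like signed score
#' (decreasing in t), replication origins and genes (density decreasing
#' in t), and a GC fraction stored on the bins.
#'
#' @slot bins [GenomeBins] with the synthetic GC fraction filled in.
#' @slot t Numeric per-bin scheduled replication-time fraction in \[0,1\].
#' @slot lad Logical per-bin lamina-association state.
#' @slot compartment Numeric per-bin signed compartment score (A > 0, B < 0).
#' @slot origins [GenomicRanges::GRanges] of origin points.
#' @slot genes [GenomicRanges::GRanges] of gene intervals.
#' @slot coupling Numeric coupling strength used by the generator.
#' @slot seed Integer generator seed.
#'
#' @seealso [makeRTTruth()]
#' @name RTTruth-class
#' @aliases RTTruth
#' @exportClass RTTruth
setClass("RTTruth", slots = c(
  bins = "GenomeBins", t = "numeric", lad = "logical",
  compartment = "numeric", origins = "GRanges", genes = "GRanges",
  coupling = "numeric", seed = "integer"
))

setValidity("RTTruth", function(object) {
  n <- length(object@bins@bins)
  msgs <- character()
  if (length(object@t) != n || length(object@lad) != n ||
      length(object@compartment) != n) {
    msgs <- c(msgs, "t, lad and compartment must have one value per bin")
  }
  if (any(object@t < 0 | object@t > 1, na.rm = TRUE)) {
    msgs <- c(msgs, "t must lie in [0,1]")
  }
  if (length(object@coupling) != 1L || object@coupling < 0) {
    msgs <- c(msgs, "coupling must be a single value >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' SimCellSet: simulated single-cell binned read counts with truth
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] (bins as rows, cells
#' as columns) holding a `counts` assay and a `trueStates` assay (0 =
#' unreplicated, 1 = replicated). `colData` records per-cell truth (`cell`,
#' `phase` in G1/S, `sFraction`), and `metadata` holds the [RTTruth], the
#' [GenomeBins], any injected copy-number events, the generator seed, and
#' the simulation parameters.
#'
#' @seealso [simulateCells()], [injectCNEvent()]
#' @name SimCellSet-class
#' @aliases SimCellSet
#' @exportClass SimCellSet
setClass("SimCellSet", contains = "RangedSummarizedExperiment")

setValidity("SimCellSet", function(object) {
  msgs <- character()
  if (!all(c("counts", "trueStates") %in% names(assays(object)))) {
    msgs <- c(msgs, "assays must contain 'counts' and 'trueStates'")
  } else {
    if (any(assay(object, "counts") < 0, na.rm = TRUE)) {
      msgs <- c(msgs, "counts must be non-negative")
    }
    st <- assay(object, "trueStates")
    if (!all(st %in% c(0L, 1L) | is.na(st))) {
      msgs <- c(msgs, "trueStates must be 0/1")
    }
  }
  if (!all(c("cell", "phase", "sFraction") %in% names(colData(object)))) {
    msgs <- c(msgs, "colData must contain cell, phase, sFraction")
  } else {
    g1 <- colData(object)$phase == "G1"
    if (any(g1) && "trueStates" %in% names(assays(object)) &&
        any(assay(object, "trueStates")[, g1, drop = FALSE] != 0L)) {
      msgs <- c(msgs, "G1 cells must have all-unreplicated truth states")
    }
  }
  if (!all(c("truth", "bins", "events", "seed") %in%
           names(metadata(object)))) {
    msgs <- c(msgs, "metadata must contain truth, bins, events, seed")
  }
  if (length(msgs)) msgs else TRUE
})

#' BinaryRT: per-cell binarized replication states
#'
#' Result of binarizing S-phase copy-ratio profiles: an integer matrix of
#' replication states (bins as rows, cells as columns; 1 = replicated, 0 =
#' unreplicated, `NA` = masked/unusable), the per-cell percent of genome
#' replicated, the cluster-centre separation of the two-means fit, and a
#' flag for cells whose separation fell below the informativeness cutoff
#' (their state columns are all `NA` and they are excluded from
#' aggregation).
#'
#' @slot states Integer matrix, bins x cells.
#' @slot percentReplicated Numeric per cell, in \[0,1\] (`NA` when
#'   non-informative).
#' @slot informative Logical per cell.
#' @slot separation Numeric per cell: distance between the two cluster
#'   centres in copy-ratio units.
#' @slot threshold Numeric per cell: midpoint of the cluster centres.
#'
#' @seealso [binarizeCells()], [aggregateProfile()], [orderCells()]
#' @name BinaryRT-class
#' @aliases BinaryRT
#' @exportClass BinaryRT
setClass("BinaryRT", slots = c(
  states = "matrix", percentReplicated = "numeric", informative = "logical",
  separation = "numeric", threshold = "numeric"
))

setValidity("BinaryRT", function(object) {
  nc <- ncol(object@states)
  if (length(object@percentReplicated) != nc ||
      length(object@informative) != nc ||
      length(object@separation) != nc || length(object@threshold) != nc) {
    return("per-cell slots must match the number of state columns")
  }
  st <- object@states
  if (!all(st %in% c(0L, 1L) | is.na(st))) {
    return("states must be 0/1/NA")
  }
  TRUE
})

#' AggregateRT: population replication-percentage profile
#'
#' Per-bin fraction of informative S cells scored replicated, the number of
#' informative (non-missing) cells entering each bin, and the early/late
#' class: early (> 50% replicated), late (< 50%), or boundary (exactly
#' 50%, excluded from comparisons).
#'
#' @slot fraction Numeric per bin in \[0,1\] (`NA` where no cell informs).
#' @slot nInformative Integer per bin.
#' @slot class Factor per bin with levels early/late/boundary.
#' @slot bins [GenomeBins].
#'
#' @seealso [aggregateProfile()], [classifyEarlyLate()]
#' @name AggregateRT-class
#' @aliases AggregateRT
#' @exportClass AggregateRT
setClass("AggregateRT", slots = c(
  fraction = "numeric", nInformative = "integer", binClass = "factor",
  bins = "GenomeBins"
))

setValidity("AggregateRT", function(object) {
  n <- length(object@bins@bins)
  msgs <- character()
  if (length(object@fraction) != n || length(object@nInformative) != n ||
      length(object@binClass) != n) {
    msgs <- c(msgs, "per-bin slots must have one value per bin")
  }
  if (any(object@fraction < 0 | object@fraction > 1, na.rm = TRUE)) {
    msgs <- c(msgs, "fraction must lie in [0,1]")
  }
  if (!identical(levels(object@binClass), c("early", "late", "boundary"))) {
    msgs <- c(msgs, "class levels must be early/late/boundary")
  }
  if (length(msgs)) msgs else TRUE
})

#' SegmentedCN: piecewise-constant copy-number segments for one cell
#'
#' Per-chromosome partition of a cell's unmasked bins into segments of
#' constant mean copy ratio, with continuous and integer copy-number calls
#' once [callCopyNumber()] has been applied.
#'
#' @slot cellId Character scalar.
#' @slot segments A data.frame with columns `chrom`, `start`, `end`
#'   (genomic, 1-based closed), `firstBin`, `lastBin` (global bin indices),
#'   `nBins`, `meanRatio`, `cnCont`, `cnInt`.
#'
#' @seealso [segmentCell()], [callCopyNumber()], [annotateBreakpoints()]
#' @name SegmentedCN-class
#' @aliases SegmentedCN
#' @exportClass SegmentedCN
setClass("SegmentedCN", slots = c(cellId = "character", segments = "data.frame"))

setValidity("SegmentedCN", function(object) {
  req <- c("chrom", "start", "end", "firstBin", "lastBin", "nBins",
           "meanRatio", "cnCont", "cnInt")
  if (!all(req %in% names(object@segments))) {
    return(paste("segments must have columns:", paste(req, collapse = ", ")))
  }
  seg <- object@segments
  if (nrow(seg) > 1L) {
    bychr <- split(seg, seg$chrom)
    for (s in bychr) {
      s <- s[order(s$firstBin), ]
      if (any(s$firstBin[-1L] <= s$lastBin[-nrow(s)])) {
        return("segments overlap within a chromosome")
      }
    }
  }
  TRUE
})

#' EnrichmentResult: site values versus a random-region null
#'
#' Comparison of a per-site quantity (gene density, origin density,
#' replication percentage, compartment score, ...) between query sites and
#' length-matched random regions, carrying the Mann-Whitney U statistic and
#' two-sided p-value and, where meaningful, an observed/expected ratio.
#'
#' @slot statistic Character: name of the compared quantity.
#' @slot siteValues,nullValues Numeric value vectors.
#' @slot observed Numeric summary (median of site values).
#' @slot oeRatio Numeric observed/expected ratio or `NA`.
#' @slot uStatistic,pValue Numeric Mann-Whitney results (U for the site
#'   group).
#' @slot nSites,nNull Integer group sizes.
#'
#' @seealso [testEnrichment()], [laminaOE()], [mannWhitney()]
#' @name EnrichmentResult-class
#' @aliases EnrichmentResult
#' @exportClass EnrichmentResult
setClass("EnrichmentResult", slots = c(
  statistic = "character", siteValues = "numeric", nullValues = "numeric",
  observed = "numeric", oeRatio = "numeric", uStatistic = "numeric",
  pValue = "numeric", nSites = "integer", nNull = "integer"
))

setValidity("EnrichmentResult", function(object) {
  msgs <- character()
  if (!is.na(object@pValue) &&
      (object@pValue <= 0 || object@pValue > 1)) {
    msgs <- c(msgs, "pValue must lie in (0,1]")
  }
  if (!is.na(object@oeRatio) && object@oeRatio < 0) {
    msgs <- c(msgs, "oeRatio must be >= 0")
  }
  if (length(msgs)) msgs else TRUE
})
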