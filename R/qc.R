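# Per-cell QC: G1-reference normalization, GC/amplification trend
# correction, MAD quality scores, phase classification.

#' Build a G1 reference profile
#'
#' Depth-normalizes each reference cell over unmasked bins and averages
#' per bin. The reference flattens copy-number, mappability and
#' amplification structure shared across cells.
#'
#' @param counts Integer matrix, bins x cells.
#' @param bins A [GenomeBins].
#' @param cells Optional column subset (names or indices) of reference
#'   cells; default all columns.
#' @param method `"mean"` (default) or `"median"` across reference cells.
#' @return Numeric per-bin reference vector.
#' @export
buildG1Reference <- function(counts, bins, cells = NULL,
                             method = c("mean", "median")) {
  method <- match.arg(method)
  stopifnot(is.matrix(counts), nrow(counts) == nBins(bins))
  if (!is.null(cells)) {
    counts <- counts[, cells, drop = FALSE]
  }
  if (ncol(counts) < 1L) {
    stop("invalid argument: reference needs >= 1 cell", call. = FALSE)
  }
  unmasked <- !binMask(bins)
  tot <- colSums(counts[unmasked, , drop = FALSE])
  if (any(tot == 0)) {
    stop("degenerate input: reference cell with zero reads", call. = FALSE)
  }
  norm <- sweep(counts, 2L, tot, `/`)
  if (method == "mean") rowMeans(norm) else apply(norm, 1L, median)
}

#' Normalize cell counts to a G1 reference
#'
#' Computes per-bin copy ratios
#' `x_b = (c_b / sum(c)) / (r_b / sum(r))` over unmasked bins with non-zero
#' reference; bins failing either condition become `NA` for the cell. A
#' ratio of 1 corresponds to the unreplicated baseline.
#'
#' @param counts Numeric vector (one cell) or matrix (bins x cells).
#' @param reference Per-bin reference from [buildG1Reference()].
#' @param bins A [GenomeBins].
#' @return Copy ratios in the same shape as `counts`.
#' @export
normalizeToReference <- function(counts, reference, bins) {
  stopifnot(length(reference) == nBins(bins))
  one <- function(c) {
    stopifnot(length(c) == nBins(bins))
    valid <- !binMask(bins) & is.finite(reference) & reference > 0
    tot <- sum(c[valid])
    if (tot == 0) {
      stop("degenerate input: cell with zero reads on usable bins",
           call. = FALSE)
    }
    refNorm <- reference / sum(reference[valid])
    x <- rep(NA_real_, nBins(bins))
    x[valid] <- (c[valid] / tot) / refNorm[valid]
    x
  }
  if (is.matrix(counts)) {
    out <- apply(counts, 2L, one)
    dimnames(out) <- dimnames(counts)
    out
  } else {
    one(counts)
  }
}

#' Correct copy ratios for a GC / amplification-efficiency trend
#'
#' Fits a local regression (loess) of copy ratio on GC fraction, divides
#' the fitted trend out and rescales to median 1. When GC is (numerically)
#' constant, only the rescaling is applied.
#'
#' @param x Copy-ratio vector or matrix (bins x cells).
#' @param gc Per-bin GC fraction.
#' @param span Loess span (default 0.75).
#' @return Corrected copy ratios, median 1 per cell, same shape as `x`.
#' @export
gcCorrect <- function(x, gc, span = 0.75) {
  one <- function(v) {
    stopifnot(length(v) == length(gc))
    usable <- is.finite(v) & is.finite(gc)
    if (sum(usable) < 30L) {
      stop("insufficient data: need >= 30 usable bins for GC correction",
           call. = FALSE)
    }
    if (stats::sd(gc[usable]) < 1e-10) {
      return(v / median(v[usable]))
    }
    fit <- loess(y ~ g, data = data.frame(y = v[usable], g = gc[usable]),
                 span = span, degree = 2,
                 control = stats::loess.control(surface = "direct"))
    gAll <- pmin(pmax(gc, min(gc[usable])), max(gc[usable]))
    trend <- predict(fit, newdata = data.frame(g = gAll))
    trend[!is.finite(trend) | trend <= 0] <- NA_real_
    out <- v / trend
    out / median(out[is.finite(out)])
  }
  if (is.matrix(x)) {
    out <- apply(x, 2L, one)
    dimnames(out) <- dimnames(x)
    out
  } else {
    one(x)
  }
}

#' Median absolute deviation quality score
#'
#' `median(|x - median(x)|)` over finite values, without the 1.4826
#' normal-consistency factor — low for G1 cells (uniform copy ratios),
#' intermediate for S cells (bimodal 1x/2x).
#'
#' @param x Copy-ratio vector for one cell.
#' @return Non-negative MAD score.
#' @export
madScore <- function(x) {
  v <- x[is.finite(x)]
  if (length(v) < 2L) {
    stop("insufficient data: MAD needs >= 2 usable bins", call. = FALSE)
  }
  median(abs(v - median(v)))
}

#' Classify cell-cycle phase from the MAD score
#'
#' G1 when `mad < g1Max`; S when `sMin <= mad <= sMax`; otherwise excluded
#' (the gray zone between `g1Max` and `sMin`, and cells above `sMax`).
#' Defaults follow the conventional shallow single-cell thresholds
#' (G1 < 0.3, S in \[0.4, 0.8\]); on synthetic data calibrate them with
#' [calibratePhaseThresholds()].
#'
#' @param mad Numeric MAD score(s), >= 0.
#' @param g1Max,sMin,sMax Thresholds (defaults 0.3, 0.4, 0.8).
#' @return Factor with levels G1/S/excluded.
#' @export
classifyPhase <- function(mad, g1Max = 0.3, sMin = 0.4, sMax = 0.8) {
  if (any(!is.finite(mad) | mad < 0)) {
    stop("invalid argument: mad must be finite and >= 0", call. = FALSE)
  }
  if (!(g1Max <= sMin && sMin <= sMax)) {
    stop("invalid argument: need g1Max <= sMin <= sMax", call. = FALSE)
  }
  out <- ifelse(mad < g1Max, "G1",
                ifelse(mad >= sMin & mad <= sMax, "S", "excluded"))
  factor(out, levels = c("G1", "S", "excluded"))
}

#' Calibrate MAD phase thresholds on (synthetic) data
#'
#' With labels (`truePhase`), picks the single MAD cutpoint maximizing
#' G1/S agreement — calibration against a labelled synthetic dataset.
#' Without labels, estimates the tight lower (G1) mode by iterative
#' trimming after a two-means split and places the cutpoint 2.5 robust
#' SDs above it. Both return the cutpoint as `g1Max = sMin` (no gray
#' zone) and `sMax` just above the largest observed score.
#'
#' @param madScores Numeric MAD scores, one per cell.
#' @param truePhase Optional factor/character of true phases ("G1"/"S").
#' @return List with `g1Max`, `sMin`, `sMax`.
#' @export
calibratePhaseThresholds <- function(madScores, truePhase = NULL) {
  stopifnot(length(madScores) >= 2L, all(is.finite(madScores)))
  sMax <- max(madScores) + 1e-6
  if (!is.null(truePhase)) {
    truePhase <- as.character(truePhase)
    stopifnot(length(truePhase) == length(madScores),
              all(truePhase %in% c("G1", "S")))
    cand <- sort(unique(madScores))
    cand <- c((cand[-1L] + cand[-length(cand)]) / 2, sMax)
    acc <- vapply(cand, function(th) {
      mean(ifelse(madScores < th, "G1", "S") == truePhase)
    }, numeric(1L))
    thr <- cand[which.max(acc)]
  } else {
    # G1 cells form a tight mode at the low end of the MAD distribution.
    # Seed its location from the quietest decile, expand once to the full
    # mode, and cut 3 robust SDs above its centre.
    sub <- madScores[madScores <= quantile(madScores, 0.1)]
    ctr <- median(madScores)
    sc <- 0.002
    for (i in 1:2) {
      ctr <- median(sub)
      sc <- max(1.4826 * median(abs(sub - ctr)), 0.002)
      sub <- madScores[madScores <= ctr + 3 * sc]
    }
    thr <- ctr + 3 * sc
  }
  list(g1Max = thr, sMin = thr, sMax = sMax)
}

#' Run the full per-cell QC stage
#'
#' Two-pass bootstrap: cells are first scored against a uniform reference
#' and the quietest decile (lowest MAD, i.e. the most G1-like cells) forms
#' the provisional G1 reference; all cells are then normalized to it,
#' MAD-scored and phase-called.  Supplying `referenceCells` skips the first
#' pass.
#'
#' GC/amplification bias shared across cells is removed by the reference
#' normalization itself (that is what the G1 reference is for). A further
#' per-cell [gcCorrect()] is available via `gcCorrectCells = TRUE` but is
#' off by default: when GC content correlates with replication timing —
#' as it does in real genomes and in the synthetic tracks — a trend fitted
#' on an S-phase cell's own ratios absorbs part of the replication signal
#' it is supposed to preserve, so per-cell trends should only be fitted on
#' non-replicating (G1) cells.
#'
#' @param counts Integer matrix, bins x cells (or a [SimCellSet]).
#' @param bins A [GenomeBins] (ignored when `counts` is a [SimCellSet]).
#' @param referenceCells Optional explicit G1 reference cell names/indices.
#' @param thresholds List with `g1Max`, `sMin`, `sMax` (defaults as in
#'   [classifyPhase()]); or `"calibrate"` to calibrate unsupervised.
#' @param gcCorrectCells Apply [gcCorrect()] to every cell individually
#'   (default `FALSE`; see Details).
#' @param span Loess span for [gcCorrect()].
#' @return List with `qc` (data.frame: cell, totalReads, mad, phase),
#'   `copyRatio` (corrected matrix), and `reference`.
#' @export
qcCells <- function(counts, bins = NULL, referenceCells = NULL,
                    thresholds = list(g1Max = 0.3, sMin = 0.4, sMax = 0.8),
                    gcCorrectCells = FALSE, span = 0.75) {
  if (is(counts, "SimCellSet")) {
    bins <- genomeBins(counts)
    counts <- assay(counts, "counts")
  }
  stopifnot(is.matrix(counts), is(bins, "GenomeBins"))
  gc <- gcContent(bins)
  hasGC <- !all(is.na(gc))
  correct <- function(x) {
    if (hasGC && isTRUE(gcCorrectCells)) gcCorrect(x, gc, span = span)
    else x
  }

  calibrated <- identical(thresholds, "calibrate")
  if (is.null(referenceCells)) {
    # uniform-reference pass: G1 cells have the flattest profiles, so the
    # lowest-MAD decile is an (almost surely) uncontaminated reference set
    x0 <- normalizeToReference(counts, rep(1, nBins(bins)), bins)
    mad0 <- apply(x0, 2L, madScore)
    referenceCells <- which(mad0 <= quantile(mad0, 0.1))
  }
  reference <- buildG1Reference(counts, bins, cells = referenceCells)
  copyRatio <- correct(normalizeToReference(counts, reference, bins))
  mads <- apply(copyRatio, 2L, madScore)
  th <- if (calibrated) calibratePhaseThresholds(mads) else thresholds
  phase <- classifyPhase(mads, th$g1Max, th$sMin, th$sMax)
  qc <- data.frame(
    cell = colnames(counts), totalReads = colSums(counts),
    mad = as.numeric(mads), phase = phase,
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(qc = qc, copyRatio = copyRatio, reference = reference,
       thresholds = th)
}

#' Write the per-cell QC table
#'
#' @param qc The `qc` data.frame from [qcCells()].
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
writeQCTable <- function(qc, path) {
  out <- qc
  out$mad <- .fmtNum(out$mad)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
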