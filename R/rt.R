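# Replication-timing inference: per-cell binarization, cell ordering,
# aggregation to a replication-percentage profile, early/late classes.

# Deterministic 1-D two-means (Lloyd) with centres initialized at the 25th
# and 75th percentiles. Returns NULL when the data cannot support two
# clusters (identical initial centres or an emptied cluster).
.twoMeans1d <- function(v, maxIter = 100L) {
  c1 <- quantile(v, 0.25, names = FALSE)
  c2 <- quantile(v, 0.75, names = FALSE)
  if (!is.finite(c1) || !is.finite(c2) || c2 - c1 < 1e-12) {
    return(NULL)
  }
  thr <- (c1 + c2) / 2
  for (i in seq_len(maxIter)) {
    hi <- v > thr
    if (!any(hi) || all(hi)) {
      return(NULL)
    }
    c1new <- mean(v[!hi])
    c2new <- mean(v[hi])
    thrNew <- (c1new + c2new) / 2
    done <- isTRUE(all.equal(c(c1, c2), c(c1new, c2new), tolerance = 1e-12))
    c1 <- c1new; c2 <- c2new; thr <- thrNew
    if (done) break
  }
  list(centers = c(c1, c2), threshold = thr)
}

# Running-median denoising of a per-bin profile, applied separately within
# each chromosome and only over finite values (masked bins stay NA).
.smoothRatios <- function(x, chrom, window) {
  if (window <= 1L) {
    return(x)
  }
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  out <- x
  for (chr in unique(chrom)) {
    idx <- which(chrom == chr & is.finite(x))
    if (length(idx) >= 2L) {
      k <- min(window, length(idx) - (1L - length(idx) %% 2L))
      out[idx] <- stats::runmed(x[idx], k, endrule = "median")
    }
  }
  out
}

#' Binarize one S-phase cell into replicated / unreplicated bins
#'
#' Denoises the copy-ratio profile with a running median (window
#' `smoothWindow` bins, per chromosome), then partitions the finite values
#' with a deterministic two-means (centres initialized at the 25th/75th
#' percentiles); bins above the midpoint of the cluster centres are
#' replicated (1), below unreplicated (0). Cells whose centre separation is
#' below `minSep` carry too little copy contrast to binarize (very early or
#' very late S, or non-replicating) and are flagged non-informative.
#'
#' @param x Corrected copy-ratio vector for one cell (`NA` = masked).
#' @param minSep Minimum centre separation in ratio units (default 0.3).
#' @param smoothWindow Running-median window in bins (default 9; 1 disables
#'   smoothing).
#' @param minBins Minimum usable bins (default 100).
#' @param chrom Optional per-bin chromosome labels; when supplied the
#'   smoothing does not run across chromosome ends.
#' @return List with `states` (integer per bin, `NA` where masked or
#'   non-informative), `percentReplicated`, `informative`, `separation`,
#'   `threshold`.
#' @export
binarizeCell <- function(x, minSep = 0.3, smoothWindow = 9L, minBins = 100L,
                         chrom = NULL) {
  usable <- is.finite(x)
  if (sum(usable) < minBins) {
    stop(sprintf("insufficient data: %d usable bins (< %d)",
                 sum(usable), minBins), call. = FALSE)
  }
  if (is.null(chrom)) {
    chrom <- rep("*", length(x))
  }
  xs <- .smoothRatios(x, chrom, smoothWindow)
  fit <- .twoMeans1d(xs[usable])
  notInformative <- list(
    states = rep(NA_integer_, length(x)), percentReplicated = NA_real_,
    informative = FALSE, separation = if (is.null(fit)) 0 else
      diff(fit$centers), threshold = NA_real_
  )
  if (is.null(fit) || diff(fit$centers) < minSep) {
    return(notInformative)
  }
  states <- rep(NA_integer_, length(x))
  states[usable] <- as.integer(xs[usable] > fit$threshold)
  list(
    states = states,
    percentReplicated = mean(states[usable]),
    informative = TRUE,
    separation = diff(fit$centers),
    threshold = fit$threshold
  )
}

#' Binarize a matrix of S-phase cells
#'
#' @param copyRatio Numeric matrix, bins x cells, of corrected copy ratios.
#' @param bins Optional [GenomeBins]; provides chromosome boundaries for the
#'   smoother.
#' @param ... Passed to [binarizeCell()].
#' @return A [BinaryRT].
#' @export
binarizeCells <- function(copyRatio, bins = NULL, ...) {
  stopifnot(is.matrix(copyRatio))
  chrom <- if (is.null(bins)) NULL
           else as.character(seqnames(binRanges(bins)))
  res <- lapply(seq_len(ncol(copyRatio)), function(j) {
    binarizeCell(copyRatio[, j], chrom = chrom, ...)
  })
  states <- vapply(res, `[[`, integer(nrow(copyRatio)), "states")
  colnames(states) <- colnames(copyRatio)
  new("BinaryRT",
      states = states,
      percentReplicated = vapply(res, `[[`, numeric(1L), "percentReplicated"),
      informative = vapply(res, `[[`, logical(1L), "informative"),
      separation = vapply(res, `[[`, numeric(1L), "separation"),
      threshold = vapply(res, `[[`, numeric(1L), "threshold"))
}

#' Aggregate binarized cells into a replication-percentage profile
#'
#' Per bin, the fraction of informative S cells whose state is non-missing
#' and replicated; a bin masked in a cell contributes to neither numerator
#' nor denominator.
#'
#' @param binary A [BinaryRT] (or a 0/1/NA state matrix, bins x cells).
#' @param bins A [GenomeBins].
#' @return An [AggregateRT].
#' @export
aggregateProfile <- function(binary, bins) {
  states <- if (is(binary, "BinaryRT")) {
    rtStates(binary)[, isInformative(binary), drop = FALSE]
  } else {
    as.matrix(binary)
  }
  if (ncol(states) == 0L) {
    stop("degenerate input: zero informative cells", call. = FALSE)
  }
  stopifnot(nrow(states) == nBins(bins))
  nInf <- as.integer(rowSums(!is.na(states)))
  frac <- rowMeans(states, na.rm = TRUE)
  frac[nInf == 0L] <- NA_real_
  new("AggregateRT", fraction = frac, nInformative = nInf,
      binClass = classifyEarlyLate(frac), bins = bins)
}

#' Classify bins as early or late replicating
#'
#' Early when more than 50% of cells are replicated, late when fewer than
#' 50%; exactly 50% is a separate boundary class excluded from
#' comparisons (both defining inequalities are strict).
#'
#' @param fraction Per-bin replication percentages in \[0,1\].
#' @return Factor with levels early/late/boundary (`NA` propagates).
#' @export
classifyEarlyLate <- function(fraction) {
  if (is(fraction, "AggregateRT")) {
    fraction <- rtFraction(fraction)
  }
  out <- ifelse(fraction > 0.5, "early",
                ifelse(fraction < 0.5, "late", "boundary"))
  factor(out, levels = c("early", "late", "boundary"))
}

#' Pearson correlation between two replication profiles
#'
#' @param a,b [AggregateRT] objects or numeric per-bin profiles on the same
#'   binning.
#' @param scope `"all"` or a chromosome name (requires [AggregateRT]
#'   inputs).
#' @param minBins Minimum shared non-missing bins (default 10).
#' @return List with `r` (Pearson correlation) and `n` (bins used).
#' @export
correlateProfiles <- function(a, b, scope = "all", minBins = 10L) {
  pick <- function(p) {
    if (is(p, "AggregateRT")) {
      v <- rtFraction(p)
      if (!identical(scope, "all")) {
        keep <- as.character(seqnames(binRanges(genomeBins(p)))) == scope
        v[!keep] <- NA_real_
      }
      v
    } else {
      as.numeric(p)
    }
  }
  va <- pick(a)
  vb <- pick(b)
  stopifnot(length(va) == length(vb))
  ok <- is.finite(va) & is.finite(vb)
  if (sum(ok) < minBins) {
    stop(sprintf("insufficient data: %d shared bins (< %d)",
                 sum(ok), minBins), call. = FALSE)
  }
  if (stats::sd(va[ok]) == 0 || stats::sd(vb[ok]) == 0) {
    stop("undefined correlation: zero variance in a profile", call. = FALSE)
  }
  list(r = cor(va[ok], vb[ok]), n = sum(ok))
}

#' Order cells by percent genome replicated
#'
#' Stable ascending sort by percent replicated, ties broken by cell
#' identifier; non-informative cells (NA percent) sort last.
#'
#' @param binary A [BinaryRT].
#' @return List with `permutation` (integer order) and `binary` (the
#'   reordered [BinaryRT]).
#' @export
orderCells <- function(binary) {
  stopifnot(is(binary, "BinaryRT"))
  ids <- colnames(binary@states)
  if (is.null(ids)) {
    ids <- as.character(seq_along(binary@percentReplicated))
  }
  perm <- order(binary@percentReplicated, ids, na.last = TRUE)
  out <- new("BinaryRT",
             states = binary@states[, perm, drop = FALSE],
             percentReplicated = binary@percentReplicated[perm],
             informative = binary@informative[perm],
             separation = binary@separation[perm],
             threshold = binary@threshold[perm])
  list(permutation = perm, binary = out)
}

#' Write a binary replication-state matrix as TSV
#'
#' @param binary A [BinaryRT].
#' @param bins A [GenomeBins].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeBinaryRT <- function(binary, bins, path) {
  stopifnot(is(binary, "BinaryRT"), nrow(rtStates(binary)) == nBins(bins))
  br <- binRanges(bins)
  df <- data.frame(chrom = as.character(seqnames(br)),
                   start = start(br) - 1L, end = end(br))
  df <- cbind(df, as.data.frame(rtStates(binary), check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Write early/late/boundary bin classes as BED
#'
#' @param aggregate An [AggregateRT].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeEarlyLateBed <- function(aggregate, path) {
  stopifnot(is(aggregate, "AggregateRT"))
  bins <- genomeBins(aggregate)
  keep <- !binMask(bins) & !is.na(rtClass(aggregate))
  writeBed(binRanges(bins)[keep], path,
           names = as.character(rtClass(aggregate))[keep],
           scores = rtFraction(aggregate)[keep])
  invisible(path)
}
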