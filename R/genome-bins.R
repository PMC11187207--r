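#' Partition a genome into fixed-width bins
#'
#' Tiles each chromosome contiguously into bins of `binSize` bp; the last
#' bin of a chromosome is shorter when the length is not a multiple of the
#' bin size. Short terminal bins are masked by default because they expose
#' fewer mappable positions than full bins.
#'
#' @param chromLengths Named numeric vector of chromosome lengths in bp.
#' @param binSize Bin width in bp (> 0).
#' @param maskShortLast Mask terminal bins shorter than `binSize`
#'   (default `TRUE`).
#' @return A [GenomeBins] with `ceiling(length / binSize)` bins per
#'   chromosome, GC unset.
#'
#' @examples
#' gb <- partitionGenome(c(chr1 = 1200000), binSize = 500000)
#' binRanges(gb)
#' @export
partitionGenome <- function(chromLengths, binSize, maskShortLast = TRUE) {
  if (is.null(names(chromLengths)) || any(!nzchar(names(chromLengths)))) {
    stop("invalid argument: chromLengths must be named", call. = FALSE)
  }
  if (anyDuplicated(names(chromLengths))) {
    stop("invalid argument: duplicated chromosome names", call. = FALSE)
  }
  .checkScalarNum(binSize, "binSize", lower = 0, strictLower = TRUE)
  if (any(!is.finite(chromLengths)) || any(chromLengths <= 0)) {
    stop("invalid argument: all chromosome lengths must be > 0", call. = FALSE)
  }
  sl <- setNames(as.integer(round(chromLengths)), names(chromLengths))
  gr <- tileGenome(sl, tilewidth = as.integer(round(binSize)),
                   cut.last.tile.in.chrom = TRUE)
  mcols(gr)$gc <- NA_real_
  mcols(gr)$mask <- maskShortLast & (width(gr) < as.integer(round(binSize)))
  new("GenomeBins", bins = gr, binSize = as.integer(round(binSize)))
}

# Map arbitrary intervals onto the seqlevels of a GenomeBins; errors when the
# track mentions chromosomes the binning does not know.
.onBins <- function(track, bins, what = "track") {
  trkChr <- as.character(unique(seqnames(track)))
  unknown <- setdiff(trkChr, chromNames(bins))
  if (length(unknown)) {
    stop(sprintf("invalid argument: %s chromosome(s) %s absent from bins",
                 what, paste(unknown, collapse = ",")), call. = FALSE)
  }
  GRanges(
    seqnames = factor(as.character(seqnames(track)),
                      levels = chromNames(bins)),
    ranges = IRanges(start(track), end(track)),
    score = if ("score" %in% names(mcols(track))) mcols(track)$score else NULL,
    seqinfo = seqinfo(binRanges(bins))
  )
}

#' Summarize an interval track per genomic bin
#'
#' @param track A [GenomicRanges::GRanges] (e.g. from
#'   [readIntervalTrack()]); its chromosomes must be a subset of the bins'.
#' @param bins A [GenomeBins].
#' @param mode One of:
#'   \describe{
#'     \item{`count`}{number of intervals whose midpoint falls in the bin —
#'       the midpoint rule prevents double counting of features spanning a
#'       bin edge;}
#'     \item{`coverage_fraction`}{summed overlapped bp divided by bin width
#'       (intervals counted with multiplicity);}
#'     \item{`mean_score`}{overlap-width-weighted mean of interval scores,
#'       `NA` for bins without overlap.}
#'   }
#' @return Numeric vector with one value per bin (masked bins included).
#' @export
binTrack <- function(track, bins,
                     mode = c("count", "coverage_fraction", "mean_score")) {
  mode <- match.arg(mode)
  stopifnot(is(track, "GRanges"), is(bins, "GenomeBins"))
  trk <- .onBins(track, bins)
  br <- binRanges(bins)
  if (mode == "count") {
    if (length(trk) == 0L) return(numeric(nBins(bins)))
    midPos <- start(trk) + width(trk) %/% 2L
    mids <- GRanges(seqnames(trk), IRanges(midPos, midPos),
                    seqinfo = seqinfo(br))
    return(as.numeric(countOverlaps(br, mids)))
  }
  out <- if (mode == "mean_score") rep(NA_real_, nBins(bins))
         else numeric(nBins(bins))
  if (length(trk) == 0L) return(out)
  if (mode == "mean_score" && !("score" %in% names(mcols(trk)))) {
    stop("invalid argument: mean_score requires a track with scores",
         call. = FALSE)
  }
  hits <- findOverlaps(br, trk)
  if (length(hits) == 0L) return(out)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  w <- width(pintersect(br[q], trk[s]))
  if (mode == "coverage_fraction") {
    bp <- tapply(w, q, sum)
    out[as.integer(names(bp))] <- as.numeric(bp) / width(br)[as.integer(names(bp))]
  } else {
    sc <- mcols(trk)$score[s]
    num <- tapply(w * sc, q, sum)
    den <- tapply(w, q, sum)
    idx <- as.integer(names(num))
    out[idx] <- as.numeric(num) / as.numeric(den)
  }
  out
}
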