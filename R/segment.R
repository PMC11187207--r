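# Copy-number segmentation and break-site annotation.

# Segment SSE over v[a:b] (inclusive, local indices) from cumulative sums.
.segSSE <- function(cs, cs2, a, b) {
  s <- cs[b + 1L] - cs[a]
  s2 <- cs2[b + 1L] - cs2[a]
  s2 - s * s / (b - a + 1L)
}

# Best single split of v[lo:hi] under a minimum segment length. Returns
# NULL when no admissible split exists, else list(split, gain) where
# `split` is the last index of the left part.
.bestSplit <- function(cs, cs2, lo, hi, minSegBins) {
  n <- hi - lo + 1L
  if (n < 2L * minSegBins) {
    return(NULL)
  }
  total <- .segSSE(cs, cs2, lo, hi)
  splits <- (lo + minSegBins - 1L):(hi - minSegBins)
  cost <- .segSSE(cs, cs2, lo, splits) + .segSSE(cs, cs2, splits + 1L, hi)
  best <- which.min(cost)
  list(split = splits[best], gain = total - cost[best])
}

# Best interior double split (i < j): segments [lo..i], [i+1..j], [j+1..hi],
# each >= minSegBins. A short copy-number event in the middle of a long
# chromosome is invisible to the best *single* split (its gain scales as
# width^2 / n) but obvious to the pair search — the circular-binary-
# segmentation idea. Exhaustive for small regions; large regions use a
# coarse grid followed by local refinement. Returns NULL or
# list(i, j, gain).
.bestDoubleSplit <- function(cs, cs2, lo, hi, minSegBins) {
  n <- hi - lo + 1L
  if (n < 3L * minSegBins) {
    return(NULL)
  }
  total <- .segSSE(cs, cs2, lo, hi)
  iLo <- lo + minSegBins - 1L
  iHi <- hi - 2L * minSegBins
  jLo <- lo + 2L * minSegBins - 1L
  jHi <- hi - minSegBins
  evalGrid <- function(is, js) {
    iM <- matrix(is, nrow = length(is), ncol = length(js))
    jM <- matrix(js, nrow = length(is), ncol = length(js), byrow = TRUE)
    sM <- cs[jM + 1L] - cs[iM + 1L]
    s2M <- cs2[jM + 1L] - cs2[iM + 1L]
    nM <- jM - iM
    cost <- outer(.segSSE(cs, cs2, lo, is), .segSSE(cs, cs2, js + 1L, hi),
                  `+`) + (s2M - sM * sM / pmax(nM, 1L))
    cost[nM < minSegBins] <- Inf
    k <- arrayInd(which.min(cost), dim(cost))
    list(i = is[k[1L]], j = js[k[2L]], cost = min(cost))
  }
  exhaustiveMax <- 250000
  if (as.numeric(iHi - iLo + 1L) * (jHi - jLo + 1L) <= exhaustiveMax) {
    best <- evalGrid(iLo:iHi, jLo:jHi)
  } else {
    step <- ceiling((iHi - iLo + 1L) / floor(sqrt(exhaustiveMax)))
    coarse <- evalGrid(unique(c(seq(iLo, iHi, by = step), iHi)),
                       unique(c(seq(jLo, jHi, by = step), jHi)))
    best <- evalGrid(
      max(iLo, coarse$i - step):min(iHi, coarse$i + step),
      max(jLo, coarse$j - step):min(jHi, coarse$j + step)
    )
    if (coarse$cost < best$cost) best <- coarse
  }
  if (!is.finite(best$cost)) {
    return(NULL)
  }
  list(i = best$i, j = best$j, gain = total - best$cost)
}

# Boundary polish: re-place each internal boundary within +/- window bins
# by least-squares assignment against trimmed (median) means of the two
# flanking segments, which are estimated away from the boundary and so are
# not diluted by misassigned edge bins.
.refineBounds <- function(v, bounds, minSegBins, window = minSegBins - 1L) {
  if (nrow(bounds) < 2L || window < 1L) {
    return(bounds)
  }
  if (length(v) >= 3L) {
    # a 3-point median passes clean steps unchanged but suppresses the
    # single-bin outliers that drag the least-squares boundary around
    v <- stats::runmed(v, 3L, endrule = "median")
  }
  for (k in seq_len(nrow(bounds) - 1L)) {
    lf <- bounds[k, 1L]; ll <- bounds[k, 2L]
    rf <- bounds[k + 1L, 1L]; rl <- bounds[k + 1L, 2L]
    mL <- median(v[lf:max(lf, ll - window)])
    mR <- median(v[min(rl, rf + window):rl])
    lo <- max(lf + minSegBins - 1L, ll - window)
    hi <- min(rl - minSegBins, ll + window)
    if (lo > hi) next
    cand <- lo:hi
    cost <- vapply(cand, function(s) {
      sum((v[lf:s] - mL)^2) + sum((v[(s + 1L):rl] - mR)^2)
    }, numeric(1L))
    s <- cand[which.min(cost)]
    bounds[k, 2L] <- s
    bounds[k + 1L, 1L] <- s + 1L
  }
  bounds
}

# Robust noise variance from first differences (a level shift contributes
# only one difference, so the estimate is insensitive to changepoints).
.noiseVar <- function(v) {
  d <- diff(v)
  if (length(d) == 0L) {
    return(0)
  }
  (1.4826 * median(abs(d - median(d))) / sqrt(2))^2
}

#' Segment one cell's copy-ratio profile
#'
#' Per chromosome, recursive splitting: each region is scanned for both the
#' best single boundary and the best pair of boundaries flanking an
#' interior segment (the circular-binary-segmentation move, without which
#' short interior events are invisible to a single-split statistic). A
#' configuration is accepted when its SSE reduction exceeds
#' `penalty * log(n) * sigma2` per changepoint, where `n` is the number of
#' usable bins on the chromosome and `sigma2` a robust noise-variance
#' estimate from first differences; the accepted parts are split
#' recursively. Deterministic. Chromosomes shorter than `2 * minSegBins`
#' usable bins yield a single segment with a warning.
#'
#' Boundaries are searched on `log2(pmax(x, logFloor))` by default: read-
#' depth ratio noise scales with the copy level, and the log transform
#' equalizes it so gain boundaries localize as sharply as losses (the same
#' reason CBS-family tools segment log ratios). Segment mean ratios are
#' always reported on the original ratio scale.
#'
#' @param x Copy-ratio vector (full length; `NA` = masked, skipped).
#' @param bins A [GenomeBins].
#' @param cellId Cell identifier stored on the result.
#' @param minSegBins Minimum bins per segment (default 5).
#' @param penalty BIC-like penalty multiplier lambda (default 4).
#' @param transform Boundary-search scale: `"log2"` (default) or
#'   `"identity"`.
#' @param logFloor Ratio floor before taking logs (default 2^-6), keeping
#'   zero-count bins finite.
#' @param refine Apply the local boundary polish (default `TRUE`).
#' @return A [SegmentedCN]; copy-number fields are `NA` until
#'   [callCopyNumber()].
#' @export
segmentCell <- function(x, bins, cellId = "cell", minSegBins = 5L,
                        penalty = 4, transform = c("log2", "identity"),
                        logFloor = 2^-6, refine = TRUE) {
  stopifnot(is(bins, "GenomeBins"), length(x) == nBins(bins))
  transform <- match.arg(transform)
  .checkScalarNum(penalty, "penalty", lower = 0)
  minSegBins <- as.integer(minSegBins)
  stopifnot(minSegBins >= 1L)
  xs <- if (transform == "log2") log2(pmax(x, logFloor)) else x
  chrom <- as.character(seqnames(binRanges(bins)))
  segs <- list()
  for (chr in chromNames(bins)) {
    idx <- which(chrom == chr & is.finite(xs))
    if (length(idx) == 0L) next
    v <- xs[idx]
    n <- length(v)
    bounds <- if (n < 2L * minSegBins) {
      warning(sprintf("chromosome %s has %d usable bins (< %d): single segment",
                      chr, n, 2L * minSegBins), call. = FALSE)
      cbind(1L, n)
    } else {
      cs <- c(0, cumsum(v))
      cs2 <- c(0, cumsum(v^2))
      thresh <- max(penalty * log(n) * .noiseVar(v), 1e-9)
      done <- list()
      queue <- list(c(1L, n))
      while (length(queue)) {
        rng <- queue[[1L]]
        queue <- queue[-1L]
        sp1 <- .bestSplit(cs, cs2, rng[1L], rng[2L], minSegBins)
        sp2 <- .bestDoubleSplit(cs, cs2, rng[1L], rng[2L], minSegBins)
        d1 <- if (is.null(sp1)) -Inf else sp1$gain - thresh
        d2 <- if (is.null(sp2)) -Inf else sp2$gain - 2 * thresh
        if (d1 <= 0 && d2 <= 0) {
          done[[length(done) + 1L]] <- rng
        } else if (d2 > d1) {
          queue <- c(queue, list(c(rng[1L], sp2$i)),
                     list(c(sp2$i + 1L, sp2$j)),
                     list(c(sp2$j + 1L, rng[2L])))
        } else {
          queue <- c(queue, list(c(rng[1L], sp1$split)),
                     list(c(sp1$split + 1L, rng[2L])))
        }
      }
      b <- do.call(rbind, done[order(vapply(done, `[[`, integer(1L), 1L))])
      if (refine) .refineBounds(v, b, minSegBins) else b
    }
    br <- binRanges(bins)
    for (i in seq_len(nrow(bounds))) {
      first <- idx[bounds[i, 1L]]
      last <- idx[bounds[i, 2L]]
      seg <- x[idx[bounds[i, 1L]:bounds[i, 2L]]]
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = chr, start = start(br)[first], end = end(br)[last],
        firstBin = first, lastBin = last,
        nBins = bounds[i, 2L] - bounds[i, 1L] + 1L,
        meanRatio = mean(seg), cnCont = NA_real_, cnInt = NA_integer_,
        stringsAsFactors = FALSE
      )
    }
  }
  new("SegmentedCN", cellId = cellId,
      segments = do.call(rbind, segs))
}

#' Call copy number on segments
#'
#' Scales segment mean ratios so the genome-wide length-weighted median
#' continuous copy number equals `baselineCn`; the integer call rounds half
#' up.
#'
#' @param seg A [SegmentedCN].
#' @param baselineCn Baseline copy number (default 2).
#' @return The [SegmentedCN] with `cnCont` and `cnInt` filled.
#' @export
callCopyNumber <- function(seg, baselineCn = 2) {
  stopifnot(is(seg, "SegmentedCN"))
  .checkScalarNum(baselineCn, "baselineCn", lower = 0, strictLower = TRUE)
  s <- seg@segments
  med <- weightedMedian(s$meanRatio, s$nBins)
  if (!is.finite(med) || med <= 0) {
    stop("degenerate input: non-positive median segment ratio", call. = FALSE)
  }
  scale <- baselineCn / med
  s$cnCont <- s$meanRatio * scale
  s$cnInt <- as.integer(floor(s$cnCont + 0.5))
  seg@segments <- s
  seg
}

#' Annotate break sites at copy-number transitions greater than one
#'
#' For each pair of adjacent segments on the same chromosome, emits a break
#' site at their shared boundary when the absolute copy-number change
#' exceeds 1 (strict; continuous copy number by default, so a change of
#' exactly 1 never qualifies). Chromosome ends never emit. The reported
#' `position` is the 0-based genomic coordinate of the boundary (the start
#' of the right segment).
#'
#' @param seg A [SegmentedCN] with copy number called, or a list of them.
#' @param useInteger Compare integer instead of continuous copy numbers
#'   (default `FALSE`).
#' @param minDelta Transition threshold (default 1, the strict ">1" rule).
#' @return data.frame with columns `cell`, `chrom`, `position`, `leftCn`,
#'   `rightCn`, `deltaCn` (zero rows when no transition qualifies).
#' @export
annotateBreakpoints <- function(seg, useInteger = FALSE, minDelta = 1) {
  if (is.list(seg)) {
    return(do.call(rbind, lapply(seg, annotateBreakpoints,
                                 useInteger = useInteger,
                                 minDelta = minDelta)))
  }
  stopifnot(is(seg, "SegmentedCN"))
  s <- seg@segments
  if (anyNA(s$cnCont)) {
    stop("copy number not called: run callCopyNumber() first", call. = FALSE)
  }
  empty <- data.frame(cell = character(), chrom = character(),
                      position = numeric(), leftCn = numeric(),
                      rightCn = numeric(), deltaCn = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(s) < 2L) {
    return(empty)
  }
  s <- s[order(s$chrom, s$firstBin), ]
  i <- seq_len(nrow(s) - 1L)
  adjacent <- s$chrom[i] == s$chrom[i + 1L]
  cn <- if (useInteger) s$cnInt else s$cnCont
  delta <- cn[i + 1L] - cn[i]
  hit <- which(adjacent & abs(delta) > minDelta)
  if (length(hit) == 0L) {
    return(empty)
  }
  data.frame(
    cell = seg@cellId, chrom = s$chrom[hit + 1L],
    position = s$start[hit + 1L] - 1,
    leftCn = cn[hit], rightCn = cn[hit + 1L], deltaCn = delta[hit],
    stringsAsFactors = FALSE
  )
}

#' Summarize karyotypes across cells
#'
#' A chromosome is called `gain`/`loss` when at least `wholeChromFraction`
#' of its segmented bins have integer copy number above/below
#' `baselineCn`; otherwise `segmental` when it carries at least one break
#' site; otherwise `euploid`. The cohort aneuploidy fraction is the share
#' of cells with at least one non-euploid chromosome.
#'
#' @param segList List of [SegmentedCN] (copy number called).
#' @param bins A [GenomeBins].
#' @param wholeChromFraction Whole-chromosome call threshold (default 0.8).
#' @param baselineCn Baseline copy number (default 2).
#' @param useInteger Passed to [annotateBreakpoints()].
#' @return List with `perChromosome` (data.frame: cell, chrom, call),
#'   `aneuploidyFraction`, and `counts` (euploid/gain/loss/segmental).
#' @export
summarizeKaryotypes <- function(segList, bins, wholeChromFraction = 0.8,
                                baselineCn = 2, useInteger = FALSE) {
  stopifnot(is.list(segList), length(segList) >= 1L)
  breaks <- annotateBreakpoints(segList, useInteger = useInteger)
  rows <- list()
  for (seg in segList) {
    s <- seg@segments
    for (chr in chromNames(bins)) {
      sc <- s[s$chrom == chr, , drop = FALSE]
      if (nrow(sc) == 0L) next
      tot <- sum(sc$nBins)
      fGain <- sum(sc$nBins[sc$cnInt > baselineCn]) / tot
      fLoss <- sum(sc$nBins[sc$cnInt < baselineCn]) / tot
      hasBreak <- any(breaks$cell == seg@cellId & breaks$chrom == chr)
      call <- if (fGain >= wholeChromFraction) "gain"
              else if (fLoss >= wholeChromFraction) "loss"
              else if (hasBreak) "segmental"
              else "euploid"
      rows[[length(rows) + 1L]] <- data.frame(
        cell = seg@cellId, chrom = chr, call = call,
        stringsAsFactors = FALSE
      )
    }
  }
  perChrom <- do.call(rbind, rows)
  byCell <- tapply(perChrom$call != "euploid", perChrom$cell, any)
  counts <- table(factor(perChrom$call,
                         levels = c("euploid", "gain", "loss", "segmental")))
  list(
    perChromosome = perChrom,
    aneuploidyFraction = mean(byCell),
    counts = counts
  )
}

#' Write per-cell segments as a BED-like TSV
#'
#' @param segList A [SegmentedCN] or list of them.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeSegmentsTSV <- function(segList, path) {
  if (is(segList, "SegmentedCN")) {
    segList <- list(segList)
  }
  rows <- lapply(segList, function(seg) {
    s <- seg@segments
    data.frame(cell = seg@cellId, chrom = s$chrom, start = s$start - 1,
               end = s$end, n_bins = s$nBins,
               mean_ratio = .fmtNum(s$meanRatio),
               cn_continuous = .fmtNum(s$cnCont), cn_integer = s$cnInt,
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write break sites as BED6
#'
#' One record per break site spanning the single base at the segment
#' boundary; name = cell id, score = |delta CN|.
#'
#' @param breaks data.frame from [annotateBreakpoints()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeBreakSitesBed <- function(breaks, path) {
  if (is.null(breaks) || nrow(breaks) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  o <- order(breaks$chrom, breaks$position)
  b <- breaks[o, ]
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t.", b$chrom, as.integer(b$position),
                     as.integer(b$position) + 1L, b$cell,
                     .fmtNum(abs(b$deltaCn))), path)
  invisible(path)
}
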