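# Synthetic-data generator: a smooth replication-timing program with coupled
# feature tracks, and single-cell binned read counts read out from it.

#' Generate a synthetic replication-timing program with coupled tracks
#'
#' Draws a Gaussian random field per chromosome, smooths it over
#' `correlationLengthBins` bins and maps it through its empirical CDF to a
#' scheduled replication-time fraction `t` in \[0,1\] (0 = earliest). Feature
#' tracks are then coupled to `t` with strength `coupling` (kappa):
#' lamina-association drawn per bin with probability
#' `plogis(4 * kappa * (t - 0.5))`, a compartment-like signed score
#' `-tanh(kappa * (t - 0.5))` plus smooth noise, origin points as a Poisson
#' process with intensity proportional to `exp(-kappa * t)`, genes likewise
#' with log-normal lengths, and a GC fraction decreasing in `t`. With
#' `coupling = 0` every track is independent of `t`.
#'
#' @param bins A [GenomeBins].
#' @param correlationLengthBins Smoothing length of the timing field, in
#'   bins (>= 1; default 20, i.e. 2 Mb at 100 kb bins).
#' @param coupling Coupling strength kappa >= 0 (default 2).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param meanOriginsPerBin,meanGenesPerBin Genome-wide mean feature
#'   densities (defaults 0.5 and 0.25 per bin).
#' @param gcBase,gcSd Centre and spread of the synthetic GC fraction
#'   (defaults 0.42 and 0.03, typical of 100 kb mammalian bins).
#' @return An [RTTruth]; its `bins` carry the synthetic GC track.
#'
#' @examples
#' gb <- partitionGenome(c(chr1 = 1e7), binSize = 1e5)
#' truth <- makeRTTruth(gb, seed = 1)
#' truth
#' @export
makeRTTruth <- function(bins, correlationLengthBins = 20L, coupling = 2,
                        seed = 1L, meanOriginsPerBin = 0.5,
                        meanGenesPerBin = 0.25, gcBase = 0.42, gcSd = 0.03) {
  stopifnot(is(bins, "GenomeBins"))
  .checkScalarNum(correlationLengthBins, "correlationLengthBins", lower = 1)
  if (!is.numeric(coupling) || length(coupling) != 1L || coupling < 0) {
    stop("invalid argument: coupling must be a single value >= 0",
         call. = FALSE)
  }
  n <- nBins(bins)
  chrom <- as.character(seqnames(binRanges(bins)))
  withSeed(seed, {
    z <- numeric(n)
    for (chr in chromNames(bins)) {
      idx <- which(chrom == chr)
      z[idx] <- gaussSmooth(rnorm(length(idx)), correlationLengthBins)
    }
    t <- (rank(z, ties.method = "first") - 0.5) / n

    lad <- runif(n) < plogis(4 * coupling * (t - 0.5))

    comp <- -tanh(coupling * (t - 0.5))
    noise <- numeric(n)
    for (chr in chromNames(bins)) {
      idx <- which(chrom == chr)
      noise[idx] <- gaussSmooth(rnorm(length(idx)), correlationLengthBins)
    }
    comp <- comp + 0.3 * noise / max(stats::sd(noise), 1e-12)

    origins <- .pointProcess(bins, exp(-coupling * t), meanOriginsPerBin)

    genes <- .pointProcess(bins, exp(-coupling * t), meanGenesPerBin,
                           lengthsBp = function(k)
                             pmax(1000, round(rlnorm(k, log(3e4), 0.8))))

    gcRaw <- -(2 * t - 1) * min(coupling, 1) +
      gaussSmooth(rnorm(n), correlationLengthBins)
    gc <- gcBase + gcSd * gcRaw / max(stats::sd(gcRaw), 1e-12)
    gc <- pmin(pmax(gc, 0.25), 0.65)
    gcContent(bins) <- gc

    new("RTTruth", bins = bins, t = t, lad = lad, compartment = comp,
        origins = origins, genes = genes, coupling = as.numeric(coupling),
        seed = as.integer(seed))
  })
}

# Poisson point/interval process over bins with per-bin relative intensity.
.pointProcess <- function(bins, intensity, meanPerBin, lengthsBp = NULL) {
  n <- nBins(bins)
  lambda <- meanPerBin * n * intensity / sum(intensity)
  k <- rpois(n, lambda)
  tot <- sum(k)
  if (tot == 0L) {
    return(GRanges(seqinfo = seqinfo(binRanges(bins))))
  }
  br <- binRanges(bins)
  binIdx <- rep(seq_len(n), k)
  pos <- start(br)[binIdx] +
    floor(runif(tot) * width(br)[binIdx])
  chr <- as.character(seqnames(br))[binIdx]
  if (is.null(lengthsBp)) {
    gr <- GRanges(chr, IRanges(pos, pos), seqinfo = seqinfo(br))
  } else {
    len <- lengthsBp(tot)
    sl <- seqlengths(br)[chr]
    gr <- GRanges(chr, IRanges(pos, pmin(pos + len - 1, sl)),
                  seqinfo = seqinfo(br))
  }
  sort(gr)
}

#' Simulate single-cell binned read counts from a timing program
#'
#' Each S cell draws an S-phase fraction `f ~ Uniform(fRange)`; a bin is
#' truly replicated when its scheduled time `t <= f`, with each state then
#' flipped independently with probability `flipRate` (replication
#' heterogeneity). Expected per-bin counts are proportional to
#' `(1 + state) * exp(N(0, ampNoiseSd)) * exp(gcCoeff * (gc - mean(gc)))` —
#' the copy-doubling signal, a log-normal whole-genome-amplification jitter,
#' and an optional exponential GC bias — rescaled so each cell's expected
#' total equals `meanReadsPerCell`. Counts are negative binomial with
#' variance `mu + mu^2 / nbDispersion` (`Inf` dispersion gives Poisson).
#' G1 cells use state 0 everywhere.
#'
#' @param truth An [RTTruth].
#' @param nG1,nS Numbers of G1 and S cells (defaults 30 and 150).
#' @param meanReadsPerCell Expected reads per cell (default 1e6).
#' @param nbDispersion NB dispersion (default 10; `Inf` = Poisson).
#' @param ampNoiseSd Log-scale amplification noise SD (default 0.1).
#' @param gcCoeff GC bias coefficient (default 0 = unbiased).
#' @param flipRate State flip probability in \[0, 0.5) (default 0.02).
#' @param fRange S-phase fraction range within (0,1) (default c(0.1, 0.9)).
#' @param seed Integer seed.
#' @return A [SimCellSet].
#' @export
simulateCells <- function(truth, nG1 = 30L, nS = 150L,
                          meanReadsPerCell = 1e6, nbDispersion = 10,
                          ampNoiseSd = 0.1, gcCoeff = 0, flipRate = 0.02,
                          fRange = c(0.1, 0.9), seed = 1L) {
  stopifnot(is(truth, "RTTruth"))
  nG1 <- as.integer(nG1); nS <- as.integer(nS)
  if (nG1 < 0L || nS < 0L || nG1 + nS < 1L) {
    stop("invalid argument: nG1 + nS must be >= 1", call. = FALSE)
  }
  if (!is.numeric(flipRate) || flipRate < 0 || flipRate >= 0.5) {
    stop("invalid argument: flipRate must lie in [0, 0.5)", call. = FALSE)
  }
  if (length(fRange) != 2L || fRange[1L] >= fRange[2L] ||
      fRange[1L] <= 0 || fRange[2L] >= 1) {
    stop("invalid argument: fRange must satisfy 0 < f_min < f_max < 1",
         call. = FALSE)
  }
  .checkScalarNum(meanReadsPerCell, "meanReadsPerCell", lower = 1)
  if (!(is.numeric(nbDispersion) && length(nbDispersion) == 1L &&
        (is.infinite(nbDispersion) || nbDispersion > 0))) {
    stop("invalid argument: nbDispersion must be > 0 or Inf", call. = FALSE)
  }
  bins <- genomeBins(truth)
  nb <- nBins(bins)
  nc <- nG1 + nS
  t <- rtProgram(truth)
  gc <- gcContent(bins)
  gcFac <- if (gcCoeff != 0 && !all(is.na(gc))) {
    g <- ifelse(is.na(gc), mean(gc, na.rm = TRUE), gc)
    exp(gcCoeff * (g - mean(g)))
  } else {
    rep(1, nb)
  }
  withSeed(seed, {
    cellIds <- sprintf("cell%03d", seq_len(nc))
    phase <- rep(c("G1", "S"), c(nG1, nS))
    f <- c(rep(NA_real_, nG1), runif(nS, fRange[1L], fRange[2L]))

    states <- matrix(0L, nrow = nb, ncol = nc,
                     dimnames = list(NULL, cellIds))
    if (nS > 0L) {
      base <- outer(t, f[(nG1 + 1L):nc], `<=`)
      if (flipRate > 0) {
        flips <- matrix(runif(nb * nS) < flipRate, nrow = nb)
        base <- xor(base, flips)
      }
      states[, (nG1 + 1L):nc] <- base + 0L
    }

    mu <- (1 + states) * gcFac
    if (ampNoiseSd > 0) {
      mu <- mu * exp(matrix(rnorm(nb * nc, 0, ampNoiseSd), nrow = nb))
    }
    mu <- sweep(mu, 2L, colSums(mu), `/`) * meanReadsPerCell
    counts <- if (is.infinite(nbDispersion)) {
      matrix(rpois(nb * nc, mu), nrow = nb)
    } else {
      matrix(rnbinom(nb * nc, mu = mu, size = nbDispersion), nrow = nb)
    }
    storage.mode(counts) <- "integer"
    colnames(counts) <- cellIds

    se <- SummarizedExperiment(
      assays = list(counts = counts, trueStates = states),
      rowRanges = binRanges(bins),
      colData = DataFrame(cell = cellIds, phase = phase, sFraction = f,
                          row.names = cellIds),
      metadata = list(
        truth = truth, bins = bins,
        events = data.frame(cell = character(), chrom = character(),
                            start = numeric(), end = numeric(),
                            deltaCn = numeric(), baselineCn = numeric(),
                            stringsAsFactors = FALSE),
        seed = as.integer(seed),
        params = list(nG1 = nG1, nS = nS,
                      meanReadsPerCell = meanReadsPerCell,
                      nbDispersion = nbDispersion, ampNoiseSd = ampNoiseSd,
                      gcCoeff = gcCoeff, flipRate = flipRate,
                      fRange = fRange)
      )
    )
    out <- new("SimCellSet", se)
    validObject(out)
    out
  })
}

#' Inject a copy-number event into one simulated cell
#'
#' Multiplies the cell's counts in the region by
#' `(baselineCn + deltaCn) / baselineCn` with stochastic rounding, and
#' appends the event to the recorded truth. Whole-chromosome events are
#' requested by passing the chromosome name as `region`.
#'
#' @param x A [SimCellSet].
#' @param cellId Cell identifier (a `colData(x)$cell` entry).
#' @param region A single-range [GenomicRanges::GRanges], or a chromosome
#'   name for a whole-chromosome event.
#' @param deltaCn Signed integer copy-number change (non-zero;
#'   `baselineCn + deltaCn >= 0`).
#' @param baselineCn Baseline copy number (default 2).
#' @param seed Optional seed for the stochastic rounding.
#' @return The modified [SimCellSet].
#' @export
injectCNEvent <- function(x, cellId, region, deltaCn, baselineCn = 2,
                          seed = NULL) {
  stopifnot(is(x, "SimCellSet"))
  if (!cellId %in% colData(x)$cell) {
    stop(sprintf("invalid argument: unknown cell '%s'", cellId),
         call. = FALSE)
  }
  if (!is.numeric(deltaCn) || length(deltaCn) != 1L ||
      deltaCn != round(deltaCn) || deltaCn == 0) {
    stop("invalid argument: deltaCn must be a non-zero integer",
         call. = FALSE)
  }
  if (baselineCn + deltaCn < 0) {
    stop("invalid argument: baselineCn + deltaCn must be >= 0",
         call. = FALSE)
  }
  bins <- genomeBins(x)
  if (is.character(region)) {
    if (length(region) != 1L || !region %in% chromNames(bins)) {
      stop(sprintf("invalid argument: unknown chromosome '%s'",
                   paste(region, collapse = ",")), call. = FALSE)
    }
    region <- GRanges(region,
                      IRanges(1L, chromLengths(bins)[[region]]))
  }
  stopifnot(is(region, "GRanges"), length(region) == 1L)
  chr <- as.character(seqnames(region))
  if (!chr %in% chromNames(bins) ||
      start(region) < 1L || end(region) > chromLengths(bins)[[chr]]) {
    stop("invalid argument: region outside the genome", call. = FALSE)
  }
  hitBins <- which(countOverlaps(binRanges(bins), .onBins(region, bins)) > 0L)
  m <- (baselineCn + deltaCn) / baselineCn
  cnt <- assay(x, "counts")
  v <- as.numeric(cnt[hitBins, cellId]) * m
  withSeed(seed, {
    lo <- floor(v)
    cnt[hitBins, cellId] <- as.integer(lo + rbinom(length(v), 1L, v - lo))
  })
  assays(x)$counts <- cnt
  ev <- metadata(x)$events
  metadata(x)$events <- rbind(ev, data.frame(
    cell = cellId, chrom = chr, start = start(region), end = end(region),
    deltaCn = deltaCn, baselineCn = baselineCn, stringsAsFactors = FALSE
  ))
  x
}
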