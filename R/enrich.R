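# Feature enrichment at sites versus length-matched random regions.

#' Sample length-matched random regions
#'
#' For each query length, draws an interval uniformly over all genomic
#' positions where it fits entirely inside an unmasked stretch (masked bins
#' are avoided by construction, so no rejection loop is needed; an
#' unsatisfiable length raises an error naming it). Deterministic given the
#' seed.
#'
#' @param queryLengths Interval lengths in bp to match (one random interval
#'   per entry).
#' @param bins A [GenomeBins]; its mask defines the admissible territory.
#' @param nSets Number of independent sets (default 1).
#' @param seed Integer seed.
#' @return A [GenomicRanges::GRanges] when `nSets = 1`, else a list of
#'   them.
#' @export
sampleRandomRegions <- function(queryLengths, bins, nSets = 1L, seed = 1L) {
  stopifnot(is(bins, "GenomeBins"), length(queryLengths) >= 1L)
  queryLengths <- as.numeric(queryLengths)
  if (any(!is.finite(queryLengths) | queryLengths < 1)) {
    stop("invalid argument: lengths must be >= 1 bp", call. = FALSE)
  }
  stretches <- reduce(binRanges(bins)[!binMask(bins)])
  if (length(stretches) == 0L) {
    stop("sampling failure: the genome is fully masked", call. = FALSE)
  }
  sw <- width(stretches)
  sampleSet <- function() {
    out <- vector("list", length(queryLengths))
    for (uL in unique(queryLengths)) {
      idx <- which(queryLengths == uL)
      fits <- which(sw >= uL)
      if (length(fits) == 0L) {
        stop(sprintf("sampling failure: no unmasked stretch fits length %d bp",
                     as.integer(uL)), call. = FALSE)
      }
      wts <- sw[fits] - uL + 1
      pick <- fits[sample.int(length(fits), length(idx), replace = TRUE,
                              prob = wts)]
      st <- start(stretches)[pick] +
        floor(runif(length(idx)) * (sw[pick] - uL + 1))
      gr <- GRanges(seqnames(stretches)[pick], IRanges(st, st + uL - 1),
                    seqinfo = seqinfo(binRanges(bins)))
      for (k in seq_along(idx)) out[[idx[k]]] <- gr[k]
    }
    do.call(c, out)
  }
  withSeed(seed, {
    if (nSets == 1L) sampleSet()
    else replicate(nSets, sampleSet(), simplify = FALSE)
  })
}

#' Mean per-bin value at sites
#'
#' Each site is extended by `windowBins` bins on both sides; the value is
#' the mean of the per-bin values over overlapping unmasked bins, `NA` when
#' every overlapped bin is masked or missing.
#'
#' @param sites A [GenomicRanges::GRanges].
#' @param values Numeric per-bin vector.
#' @param bins A [GenomeBins].
#' @param windowBins Extension in bins on each side (default 0).
#' @return Numeric vector, one value per site.
#' @export
valueAtSites <- function(sites, values, bins, windowBins = 0L) {
  stopifnot(is(sites, "GRanges"), length(values) == nBins(bins))
  st <- .onBins(sites, bins, what = "sites")
  if (windowBins > 0L) {
    pad <- as.integer(windowBins) * binSize(bins)
    st <- GRanges(seqnames(st),
                  IRanges(pmax(1L, start(st) - pad),
                          pmin(seqlengths(st)[as.character(seqnames(st))],
                               end(st) + pad)),
                  seqinfo = seqinfo(st))
  }
  vals <- values
  vals[binMask(bins)] <- NA_real_
  hits <- findOverlaps(st, binRanges(bins))
  out <- rep(NA_real_, length(st))
  if (length(hits)) {
    agg <- tapply(vals[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits),
                  function(v) if (all(is.na(v))) NA_real_
                              else mean(v, na.rm = TRUE))
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}

#' Lamina-association observed/expected ratio
#'
#' Observed: fraction of sites overlapping a lamina-associated domain by at
#' least `minOverlapBp`. Expected: LAD bp coverage fraction of the unmasked
#' genome. OE > 1 indicates more lamina association than random.
#'
#' @param sites A [GenomicRanges::GRanges].
#' @param ladTrack LAD intervals ([GenomicRanges::GRanges]).
#' @param bins A [GenomeBins].
#' @param minOverlapBp Minimum overlap to count a site as associated
#'   (default 1 bp).
#' @return List with `oe`, `observed`, `expected`, `nSites`.
#' @export
laminaOE <- function(sites, ladTrack, bins, minOverlapBp = 1L) {
  stopifnot(is(sites, "GRanges"), is(ladTrack, "GRanges"))
  st <- .onBins(sites, bins, what = "sites")
  lad <- reduce(.onBins(ladTrack, bins, what = "LAD track"))
  unmasked <- reduce(binRanges(bins)[!binMask(bins)])
  denom <- sum(as.numeric(width(unmasked)))
  if (denom == 0) {
    stop("undefined OE: the genome is fully masked", call. = FALSE)
  }
  expected <- sum(as.numeric(width(GenomicRanges::intersect(lad, unmasked)))) /
    denom
  if (expected == 0) {
    stop("undefined OE: zero expected LAD coverage", call. = FALSE)
  }
  observed <- mean(countOverlaps(st, lad, minoverlap = minOverlapBp) > 0L)
  list(oe = observed / expected, observed = observed, expected = expected,
       nSites = length(st))
}

#' Compartment score and A/B label at sites
#'
#' Per-site mean of a Hi-C-style eigenvector binned track; positive means A
#' compartment, negative means B, exactly zero (or missing) is unassigned.
#'
#' @param sites A [GenomicRanges::GRanges].
#' @param eigenvector Numeric per-bin eigenvector values.
#' @param bins A [GenomeBins].
#' @return data.frame with columns `value` and `label` (A/B/unassigned).
#' @export
compartmentAtSites <- function(sites, eigenvector, bins) {
  v <- valueAtSites(sites, eigenvector, bins)
  label <- ifelse(is.na(v) | v == 0, "unassigned",
                  ifelse(v > 0, "A", "B"))
  data.frame(value = v, label = factor(label, levels = c("A", "B", "unassigned")),
             stringsAsFactors = FALSE)
}

#' Long-gene and long-intergenic region sets
#'
#' Long genes are gene intervals longer than `minGeneBp`; intergenic
#' regions are the gaps between merged gene intervals (including chromosome
#' ends) longer than `minIntergenicBp`.
#'
#' @param genes Gene intervals ([GenomicRanges::GRanges]).
#' @param bins A [GenomeBins] (supplies chromosome bounds).
#' @param minGeneBp Long-gene cutoff (default 500 kb, strict >).
#' @param minIntergenicBp Intergenic cutoff (default 1 Mb, strict >).
#' @return List with `longGenes` and `longIntergenic` (`GRanges`).
#' @export
deriveRegionSets <- function(genes, bins, minGeneBp = 5e5,
                             minIntergenicBp = 1e6) {
  stopifnot(is(genes, "GRanges"), is(bins, "GenomeBins"))
  if (length(genes) == 0L) {
    warning("empty gene track: returning empty region sets", call. = FALSE)
    empty <- GRanges(seqinfo = seqinfo(binRanges(bins)))
    return(list(longGenes = empty, longIntergenic = empty))
  }
  g <- .onBins(genes, bins, what = "genes")
  longGenes <- g[width(g) > minGeneBp]
  merged <- reduce(g)
  genome <- GRanges(chromNames(bins),
                    IRanges(1L, chromLengths(bins)[chromNames(bins)]),
                    seqinfo = seqinfo(binRanges(bins)))
  gaps <- GenomicRanges::setdiff(genome, merged)
  list(longGenes = longGenes,
       longIntergenic = gaps[width(gaps) > minIntergenicBp])
}

#' Compare a per-bin quantity at sites against a random-region null
#'
#' Convenience wrapper: evaluates `values` at the sites and at
#' length-matched random regions (`nNull` regions, lengths recycled from
#' the sites) and runs a two-sided Mann-Whitney test.
#'
#' @param sites Query sites ([GenomicRanges::GRanges]).
#' @param values Numeric per-bin vector.
#' @param bins A [GenomeBins].
#' @param statistic Name of the compared quantity.
#' @param nNull Number of random regions (default 360).
#' @param seed Seed for the random regions.
#' @param windowBins Passed to [valueAtSites()].
#' @param oeRatio Optional observed/expected ratio to store.
#' @return An [EnrichmentResult].
#' @export
testEnrichment <- function(sites, values, bins, statistic = "value",
                           nNull = 360L, seed = 1L, windowBins = 0L,
                           oeRatio = NA_real_) {
  stopifnot(is(sites, "GRanges"), length(sites) >= 1L)
  siteValues <- valueAtSites(sites, values, bins, windowBins = windowBins)
  lens <- rep(width(sites), length.out = nNull)
  null <- sampleRandomRegions(lens, bins, seed = seed)
  nullValues <- valueAtSites(null, values, bins, windowBins = windowBins)
  mw <- mannWhitney(siteValues, nullValues)
  new("EnrichmentResult",
      statistic = statistic, siteValues = siteValues,
      nullValues = nullValues,
      observed = median(siteValues, na.rm = TRUE),
      oeRatio = as.numeric(oeRatio), uStatistic = as.numeric(mw$U),
      pValue = mw$p, nSites = length(sites), nNull = as.integer(nNull))
}

#' Write enrichment results as TSV
#'
#' @param results A list of [EnrichmentResult] objects.
#' @param path Output path.
#' @param seed Seed recorded in the table.
#' @return Invisibly, the path.
#' @export
writeEnrichmentTSV <- function(results, path, seed = NA_integer_) {
  rows <- lapply(results, as.data.frame)
  df <- do.call(rbind, rows)
  df$seed <- seed
  num <- vapply(df, is.numeric, logical(1L)) & names(df) != "seed"
  df[num] <- lapply(df[num], .fmtNum)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
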