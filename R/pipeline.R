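# End-to-end orchestration of the synthetic pipeline with deterministic
# seeds, per-stage logging, and plain-text outputs.

#' Default pipeline configuration
#'
#' Desk-scale defaults: 2 chromosomes x 100 Mb at 100 kb bins, 30 G1 + 150
#' S cells at 1M reads each, NB dispersion 10, amplification noise 0.1,
#' flip rate 0.02; 20 cells receive one random segmental copy-number event
#' (|delta CN| = 2, 30 bins) so the break-site stage has signal; QC
#' thresholds calibrated on the synthetic MAD distribution; 360 random
#' null regions for enrichment.
#'
#' @param seed Master seed; every stage derives its own seed from it.
#' @return Nested named list understood by [runPipeline()].
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(
      nChrom = 2L, chromLengthBp = 1e8, binSizeBp = 1e5,
      correlationLengthBins = 20L, coupling = 2,
      nG1 = 30L, nS = 150L, meanReadsPerCell = 1e6, nbDispersion = 10,
      ampNoiseSd = 0.1, gcCoeff = 0, flipRate = 0.02, fRange = c(0.1, 0.9),
      nEventCells = 20L, eventDeltaCn = c(-2L, 2L), eventBins = 30L
    ),
    qc = list(calibrate = TRUE, g1Max = 0.3, sMin = 0.4, sMax = 0.8,
              gcSpan = 0.75),
    rt = list(minSep = 0.3, smoothWindow = 9L, minBins = 100L),
    cnv = list(minSegBins = 5L, penalty = 4, baselineCn = 2,
               useInteger = FALSE),
    enrich = list(nNull = 360L, windowBins = 0L)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values in the file override [defaultPipelineConfig()]; unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  base <- defaultPipelineConfig()
  merge <- function(base, user, prefix = "") {
    for (k in names(user)) {
      if (!k %in% names(base)) {
        stop(sprintf("validation error: unknown config key '%s%s'",
                     prefix, k), call. = FALSE)
      }
      if (is.list(base[[k]]) && is.list(user[[k]])) {
        base[[k]] <- merge(base[[k]], user[[k]], paste0(prefix, k, "."))
      } else {
        base[[k]] <- user[[k]]
      }
    }
    base
  }
  merge(base, user)
}

#' Validate a pipeline configuration
#'
#' @param config Configuration list.
#' @return Invisibly `TRUE`; errors describe the offending key.
#' @export
validatePipelineConfig <- function(config) {
  need <- function(cond, msg) {
    if (!isTRUE(cond)) stop(paste("validation error:", msg), call. = FALSE)
  }
  need(all(c("seed", "simulate", "qc", "rt", "cnv", "enrich") %in%
             names(config)), "missing top-level sections")
  s <- config$simulate
  need(s$nChrom >= 1 && s$chromLengthBp > 0 && s$binSizeBp > 0,
       "simulate: genome dimensions must be positive")
  need(s$nG1 + s$nS >= 1, "simulate: nG1 + nS must be >= 1")
  need(s$flipRate >= 0 && s$flipRate < 0.5,
       "simulate: flipRate must lie in [0, 0.5)")
  need(length(s$fRange) == 2 && s$fRange[1] < s$fRange[2] &&
         s$fRange[1] > 0 && s$fRange[2] < 1,
       "simulate: fRange must satisfy 0 < f_min < f_max < 1")
  need(config$qc$g1Max <= config$qc$sMin,
       "qc: g1Max must not exceed sMin")
  need(config$rt$minSep > 0, "rt: minSep must be > 0")
  need(config$cnv$minSegBins >= 1 && config$cnv$penalty >= 0,
       "cnv: bad segmentation parameters")
  need(config$enrich$nNull >= 1, "enrich: nNull must be >= 1")
  invisible(TRUE)
}

.stageLog <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full synthetic analysis pipeline
#'
#' Simulate -> QC -> replication timing -> copy-number segmentation and
#' break sites -> enrichment, writing every result as sorted plain text
#' (TSV/BED/bedGraph) plus a YAML manifest of parameters and seeds. Reruns
#' with an identical configuration are byte-identical.
#'
#' @param config Configuration list from [defaultPipelineConfig()] or
#'   [readPipelineConfig()].
#' @param outDir Output directory (created if absent).
#' @return Invisibly, a list with the main in-memory results and the
#'   output file paths.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir) {
  validatePipelineConfig(config)
  if (!dir.exists(outDir)) {
    dir.create(outDir, recursive = TRUE)
  }
  paths <- list()
  outfile <- function(name) {
    paths[[name]] <<- file.path(outDir, name)
    paths[[name]]
  }
  seed <- as.integer(config$seed)

  ## stage: simulate -------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  s <- config$simulate
  chromLengths <- setNames(rep(s$chromLengthBp, s$nChrom),
                           sprintf("chr%d", seq_len(s$nChrom)))
  bins <- partitionGenome(chromLengths, s$binSizeBp)
  truth <- makeRTTruth(bins, correlationLengthBins = s$correlationLengthBins,
                       coupling = s$coupling, seed = seed)
  bins <- genomeBins(truth)
  cells <- simulateCells(truth, nG1 = s$nG1, nS = s$nS,
                         meanReadsPerCell = s$meanReadsPerCell,
                         nbDispersion = s$nbDispersion,
                         ampNoiseSd = s$ampNoiseSd, gcCoeff = s$gcCoeff,
                         flipRate = s$flipRate, fRange = s$fRange,
                         seed = seed + 1L)
  if (s$nEventCells > 0L) {
    cells <- withSeed(seed + 2L, {
      ids <- sample(colnames(cells), min(s$nEventCells, ncol(cells)))
      for (id in ids) {
        chr <- sample(chromNames(bins), 1L)
        span <- s$eventBins * binSize(bins)
        maxStart <- chromLengths(bins)[[chr]] - span
        st <- 1L + floor(runif(1L) * maxStart)
        region <- GRanges(chr, IRanges(st, st + span - 1L))
        delta <- sample(s$eventDeltaCn, 1L)
        cells <- injectCNEvent(cells, id, region, delta)
      }
      cells
    })
  }
  writeCountsTSV(assay(cells, "counts"), bins, outfile("counts.tsv"))
  truthDf <- data.frame(cell = colData(cells)$cell,
                        phase = as.character(cellPhase(cells)),
                        s_fraction = .fmtNum(sFraction(cells)))
  write.table(truthDf, outfile("cell_truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cnEvents(cells), outfile("events_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeBedGraph(rtProgram(truth), bins, outfile("rt_truth.bedgraph"))
  writeBedGraph(gcContent(bins), bins, outfile("gc.bedgraph"))
  writeBedGraph(compartmentScore(truth), bins,
                outfile("compartment.bedgraph"))
  writeBed(reduce(binRanges(bins)[ladStates(truth)]), outfile("lads.bed"))
  writeBed(originSites(truth), outfile("origins.bed"))
  writeBed(geneAnnotation(truth), outfile("genes.bed"))
  .stageLog("simulate", "%d bins x %d cells, %d CN events (%.1fs)",
            nBins(bins), ncol(cells), nrow(cnEvents(cells)),
            proc.time()[["elapsed"]] - t0)

  ## stage: qc -------------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  thr <- if (isTRUE(config$qc$calibrate)) "calibrate"
         else config$qc[c("g1Max", "sMin", "sMax")]
  qc <- qcCells(cells, thresholds = thr, span = config$qc$gcSpan)
  writeQCTable(qc$qc, outfile("qc.tsv"))
  .stageLog("qc", "%d G1, %d S, %d excluded (%.1fs)",
            sum(qc$qc$phase == "G1"), sum(qc$qc$phase == "S"),
            sum(qc$qc$phase == "excluded"), proc.time()[["elapsed"]] - t0)

  ## stage: rt -------------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  sCells <- qc$qc$cell[qc$qc$phase == "S"]
  if (length(sCells) == 0L) {
    stop("stage rt: no S-phase cells after QC", call. = FALSE)
  }
  binary <- binarizeCells(qc$copyRatio[, sCells, drop = FALSE], bins = bins,
                          minSep = config$rt$minSep,
                          smoothWindow = config$rt$smoothWindow,
                          minBins = config$rt$minBins)
  binary <- orderCells(binary)$binary
  aggregate <- aggregateProfile(binary, bins)
  writeBinaryRT(binary, bins, outfile("binary_states.tsv"))
  writeBedGraph(rtFraction(aggregate), bins, outfile("aggregate_rt.bedgraph"))
  writeEarlyLateBed(aggregate, outfile("early_late.bed"))
  .stageLog("rt", "%d informative S cells; %d early / %d late bins (%.1fs)",
            sum(isInformative(binary)),
            sum(rtClass(aggregate) == "early", na.rm = TRUE),
            sum(rtClass(aggregate) == "late", na.rm = TRUE),
            proc.time()[["elapsed"]] - t0)

  ## stage: cnv / breaks ---------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  # copy number is read out on non-replicating (G1) cells, where segment
  # structure is not confounded by replication bimodality
  cnCells <- qc$qc$cell[qc$qc$phase == "G1"]
  if (length(cnCells) == 0L) {
    cnCells <- qc$qc$cell
  }
  segs <- lapply(cnCells, function(id) {
    callCopyNumber(
      segmentCell(qc$copyRatio[, id], bins, cellId = id,
                  minSegBins = config$cnv$minSegBins,
                  penalty = config$cnv$penalty),
      baselineCn = config$cnv$baselineCn
    )
  })
  breaks <- annotateBreakpoints(segs, useInteger = config$cnv$useInteger)
  karyo <- summarizeKaryotypes(segs, bins,
                               baselineCn = config$cnv$baselineCn,
                               useInteger = config$cnv$useInteger)
  writeSegmentsTSV(segs, outfile("segments.tsv"))
  writeBreakSitesBed(breaks, outfile("break_sites.bed"))
  write.table(karyo$perChromosome, outfile("karyotype.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  .stageLog("breaks", "%d break site(s); aneuploidy fraction %.2f (%.1fs)",
            nrow(breaks), karyo$aneuploidyFraction,
            proc.time()[["elapsed"]] - t0)

  ## stage: enrich ---------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  enrichment <- list()
  if (nrow(breaks) > 0L) {
    sites <- GRanges(breaks$chrom,
                     IRanges(pmax(1, breaks$position), pmax(1, breaks$position) + 1),
                     seqinfo = seqinfo(binRanges(bins)))
    geneDensity <- binTrack(geneAnnotation(truth), bins, "count")
    originDensity <- binTrack(originSites(truth), bins, "count")
    enrichment <- list(
      testEnrichment(sites, geneDensity, bins, "gene_density",
                     nNull = config$enrich$nNull, seed = seed + 3L,
                     windowBins = config$enrich$windowBins),
      testEnrichment(sites, originDensity, bins, "origin_density",
                     nNull = config$enrich$nNull, seed = seed + 4L,
                     windowBins = config$enrich$windowBins),
      testEnrichment(sites, rtFraction(aggregate), bins,
                     "replication_percentage",
                     nNull = config$enrich$nNull, seed = seed + 5L,
                     windowBins = config$enrich$windowBins,
                     oeRatio = laminaOE(sites,
                                        reduce(binRanges(bins)[ladStates(truth)]),
                                        bins)$oe),
      testEnrichment(sites, compartmentScore(truth), bins,
                     "compartment_score",
                     nNull = config$enrich$nNull, seed = seed + 6L,
                     windowBins = config$enrich$windowBins)
    )
    writeEnrichmentTSV(enrichment, outfile("enrichment.tsv"),
                       seed = seed + 3L)
  } else {
    writeLines(paste("statistic", "site_median", "null_median", "oe_ratio",
                     "u_statistic", "p_two_sided", "n_sites", "n_null",
                     "seed", sep = "\t"), outfile("enrichment.tsv"))
  }
  .stageLog("enrich", "%d feature comparison(s) at %d break site(s) (%.1fs)",
            length(enrichment), nrow(breaks), proc.time()[["elapsed"]] - t0)

  ## manifest --------------------------------------------------------------
  manifest <- list(
    package = "scEmbryoRT",
    version = as.character(utils::packageVersion("scEmbryoRT")),
    seed = seed,
    config = config,
    outputs = sort(names(paths))
  )
  yaml::write_yaml(manifest, outfile("manifest.yaml"))

  invisible(list(bins = bins, truth = truth, cells = cells, qc = qc,
                 binary = binary, aggregate = aggregate, segments = segs,
                 breaks = breaks, karyotype = karyo,
                 enrichment = enrichment, paths = paths))
}
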