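# Accessors and show() methods.

#' @rdname GenomeBins-class
#' @export
setMethod("binRanges", "GenomeBins", function(x) x@bins)

#' @rdname GenomeBins-class
#' @export
setMethod("binSize", "GenomeBins", function(x) x@binSize)

#' @rdname GenomeBins-class
#' @export
setMethod("nBins", "GenomeBins", function(x) length(x@bins))

#' @rdname GenomeBins-class
#' @export
setMethod("gcContent", "GenomeBins", function(x) mcols(x@bins)$gc)

#' @rdname GenomeBins-class
#' @export
setReplaceMethod("gcContent", "GenomeBins", function(x, value) {
  stopifnot(length(value) == length(x@bins))
  mcols(x@bins)$gc <- as.numeric(value)
  validObject(x)
  x
})

#' @rdname GenomeBins-class
#' @export
setMethod("binMask", "GenomeBins", function(x) mcols(x@bins)$mask)

#' @rdname GenomeBins-class
#' @export
setReplaceMethod("binMask", "GenomeBins", function(x, value) {
  stopifnot(length(value) == length(x@bins))
  mcols(x@bins)$mask <- as.logical(value)
  validObject(x)
  x
})

#' @rdname GenomeBins-class
#' @export
setMethod("chromNames", "GenomeBins", function(x) seqlevels(x@bins))

#' @rdname GenomeBins-class
#' @export
setMethod("chromLengths", "GenomeBins", function(x) seqlengths(x@bins))

setMethod("show", "GenomeBins", function(object) {
  cat(sprintf(
    "GenomeBins: %d bins of %s bp on %d chromosome(s); %d masked\n",
    nBins(object), format(binSize(object), big.mark = ","),
    length(chromNames(object)), sum(binMask(object))
  ))
  if (all(is.na(gcContent(object)))) {
    cat("  gc: not set\n")
  } else {
    cat(sprintf("  gc: mean %.3f\n", mean(gcContent(object), na.rm = TRUE)))
  }
})

#' @rdname RTTruth-class
#' @export
setMethod("genomeBins", "RTTruth", function(x) x@bins)

#' @rdname RTTruth-class
#' @export
setMethod("rtProgram", "RTTruth", function(x) x@t)

#' @rdname RTTruth-class
#' @export
setMethod("ladStates", "RTTruth", function(x) x@lad)

#' @rdname RTTruth-class
#' @export
setMethod("compartmentScore", "RTTruth", function(x) x@compartment)

#' @rdname RTTruth-class
#' @export
setMethod("originSites", "RTTruth", function(x) x@origins)

#' @rdname RTTruth-class
#' @export
setMethod("geneAnnotation", "RTTruth", function(x) x@genes)

setMethod("show", "RTTruth", function(object) {
  cat(sprintf(
    "RTTruth: %d bins; coupling %.2f; %d origins; %d genes; LAD fraction %.2f\n",
    nBins(object@bins), object@coupling, length(object@origins),
    length(object@genes), mean(object@lad)
  ))
})

#' @rdname SimCellSet-class
#' @export
setMethod("genomeBins", "SimCellSet", function(x) metadata(x)$bins)

#' @rdname SimCellSet-class
#' @export
setMethod("rtTruth", "SimCellSet", function(x) metadata(x)$truth)

#' @rdname SimCellSet-class
#' @export
setMethod("trueStates", "SimCellSet", function(x) assay(x, "trueStates"))

#' @rdname SimCellSet-class
#' @export
setMethod("cellPhase", "SimCellSet", function(x) colData(x)$phase)

#' @rdname SimCellSet-class
#' @export
setMethod("sFraction", "SimCellSet", function(x) colData(x)$sFraction)

#' @rdname SimCellSet-class
#' @export
setMethod("cnEvents", "SimCellSet", function(x) metadata(x)$events)

setMethod("show", "SimCellSet", function(object) {
  ph <- table(cellPhase(object))
  cat(sprintf(
    "SimCellSet: %d bins x %d cells (%s); %d injected CN event(s)\n",
    nrow(object), ncol(object),
    paste(sprintf("%s=%d", names(ph), as.integer(ph)), collapse = ", "),
    nrow(cnEvents(object))
  ))
})

#' @rdname BinaryRT-class
#' @export
setMethod("rtStates", "BinaryRT", function(x) x@states)

#' @rdname BinaryRT-class
#' @export
setMethod("percentReplicated", "BinaryRT", function(x) x@percentReplicated)

#' @rdname BinaryRT-class
#' @export
setMethod("isInformative", "BinaryRT", function(x) x@informative)

setMethod("show", "BinaryRT", function(object) {
  cat(sprintf(
    "BinaryRT: %d bins x %d cells; %d informative\n",
    nrow(object@states), ncol(object@states), sum(object@informative)
  ))
})

#' @rdname AggregateRT-class
#' @export
setMethod("rtFraction", "AggregateRT", function(x) x@fraction)

#' @rdname AggregateRT-class
#' @export
setMethod("rtClass", "AggregateRT", function(x) x@binClass)

#' @rdname AggregateRT-class
#' @export
setMethod("nInformative", "AggregateRT", function(x) x@nInformative)

#' @rdname AggregateRT-class
#' @export
setMethod("genomeBins", "AggregateRT", function(x) x@bins)

setMethod("show", "AggregateRT", function(object) {
  tb <- table(object@binClass)
  cat(sprintf(
    "AggregateRT: %d bins (early %d, late %d, boundary %d)\n",
    nBins(object@bins), tb[["early"]], tb[["late"]], tb[["boundary"]]
  ))
})

#' @rdname SegmentedCN-class
#' @export
setMethod("cnSegments", "SegmentedCN", function(x) x@segments)

#' @rdname SegmentedCN-class
#' @export
setMethod("cellId", "SegmentedCN", function(x) x@cellId)

setMethod("show", "SegmentedCN", function(object) {
  cat(sprintf(
    "SegmentedCN [%s]: %d segment(s) on %d chromosome(s)%s\n",
    object@cellId, nrow(object@segments),
    length(unique(object@segments$chrom)),
    if (all(is.na(object@segments$cnCont))) " (copy number not called)" else ""
  ))
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf(
    "EnrichmentResult [%s]: n_sites=%d n_null=%d U=%.1f p=%.3g%s\n",
    object@statistic, object@nSites, object@nNull, object@uStatistic,
    object@pValue,
    if (is.na(object@oeRatio)) "" else sprintf(" OE=%.3f", object@oeRatio)
  ))
})

#' Extract an EnrichmentResult as a one-row data.frame
#'
#' @param x An [EnrichmentResult].
#' @param row.names,optional,... Passed over from the generic (unused).
#' @return A one-row data.frame with the statistic name, site/null medians,
#'   OE ratio, U, p and group sizes.
#' @export
as.data.frame.EnrichmentResult <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(
    statistic = x@statistic,
    site_median = median(x@siteValues, na.rm = TRUE),
    null_median = median(x@nullValues, na.rm = TRUE),
    oe_ratio = x@oeRatio,
    u_statistic = x@uStatistic,
    p_two_sided = x@pValue,
    n_sites = x@nSites,
    n_null = x@nNull,
    stringsAsFactors = FALSE
  )
}
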