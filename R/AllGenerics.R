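#' @import methods
#' @importFrom S4Vectors metadata metadata<- mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges tileGenome findOverlaps countOverlaps
#'   pintersect reduce width start end seqnames strand
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom GenomeInfoDb seqlengths seqlevels seqlevels<- seqinfo Seqinfo
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- rowRanges colData
#' @importFrom stats median mad quantile rnorm runif rbinom rpois rnbinom
#'   rlnorm loess predict pnorm plogis cor setNames
#' @importFrom utils combn read.delim write.table packageVersion
NULL

#' @rdname GenomeBins-class
#' @param x An object.
#' @export
setGeneric("binRanges", function(x) standardGeneric("binRanges"))

#' @rdname GenomeBins-class
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname GenomeBins-class
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname GenomeBins-class
#' @export
setGeneric("gcContent", function(x) standardGeneric("gcContent"))

#' @rdname GenomeBins-class
#' @param value Replacement value.
#' @export
setGeneric("gcContent<-", function(x, value) standardGeneric("gcContent<-"))

#' @rdname GenomeBins-class
#' @export
setGeneric("binMask", function(x) standardGeneric("binMask"))

#' @rdname GenomeBins-class
#' @export
setGeneric("binMask<-", function(x, value) standardGeneric("binMask<-"))

#' @rdname GenomeBins-class
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname GenomeBins-class
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname RTTruth-class
#' @export
setGeneric("rtProgram", function(x) standardGeneric("rtProgram"))

#' @rdname RTTruth-class
#' @export
setGeneric("ladStates", function(x) standardGeneric("ladStates"))

#' @rdname RTTruth-class
#' @export
setGeneric("compartmentScore", function(x) standardGeneric("compartmentScore"))

#' @rdname RTTruth-class
#' @export
setGeneric("originSites", function(x) standardGeneric("originSites"))

#' @rdname RTTruth-class
#' @export
setGeneric("geneAnnotation", function(x) standardGeneric("geneAnnotation"))

#' @rdname SimCellSet-class
#' @export
setGeneric("genomeBins", function(x) standardGeneric("genomeBins"))

#' @rdname SimCellSet-class
#' @export
setGeneric("rtTruth", function(x) standardGeneric("rtTruth"))

#' @rdname SimCellSet-class
#' @export
setGeneric("trueStates", function(x) standardGeneric("trueStates"))

#' @rdname SimCellSet-class
#' @export
setGeneric("cellPhase", function(x) standardGeneric("cellPhase"))

#' @rdname SimCellSet-class
#' @export
setGeneric("sFraction", function(x) standardGeneric("sFraction"))

#' @rdname SimCellSet-class
#' @export
setGeneric("cnEvents", function(x) standardGeneric("cnEvents"))

#' @rdname BinaryRT-class
#' @export
setGeneric("rtStates", function(x) standardGeneric("rtStates"))

#' @rdname BinaryRT-class
#' @export
setGeneric("percentReplicated", function(x) standardGeneric("percentReplicated"))

#' @rdname BinaryRT-class
#' @export
setGeneric("isInformative", function(x) standardGeneric("isInformative"))

#' @rdname AggregateRT-class
#' @export
setGeneric("rtFraction", function(x) standardGeneric("rtFraction"))

#' @rdname AggregateRT-class
#' @export
setGeneric("rtClass", function(x) standardGeneric("rtClass"))

#' @rdname AggregateRT-class
#' @export
setGeneric("nInformative", function(x) standardGeneric("nInformative"))

#' @rdname SegmentedCN-class
#' @export
setGeneric("cnSegments", function(x) standardGeneric("cnSegments"))

#' @rdname SegmentedCN-class
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))
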