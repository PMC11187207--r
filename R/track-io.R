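# Plain-text genomics I/O: chromosome sizes, BED, bedGraph, count tables.
# Readers validate line by line so malformed records are reported with their
# line number; writers emit sorted, tab-separated, newline-terminated text.

#' Read a two-column chromosome-sizes table
#'
#' @param path TSV with columns name, length (no header).
#' @return Named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("chromosome-sizes file needs two columns (name, length)",
         call. = FALSE)
  }
  len <- suppressWarnings(as.numeric(df[[2L]]))
  bad <- which(!is.finite(len) | len <= 0)
  if (length(bad)) {
    stop(sprintf("parse error at line %d: bad chromosome length '%s'",
                 bad[1L], df[[2L]][bad[1L]]), call. = FALSE)
  }
  setNames(len, as.character(df[[1L]]))
}

#' Read a BED or bedGraph interval track
#'
#' Coordinates on disk are 0-based half-open (the BED convention) unless
#' `oneBased = TRUE`, in which case they are treated as 1-based closed and
#' converted. Internally intervals are returned as a
#' [GenomicRanges::GRanges] (1-based closed). BED column 4 is stored as
#' `name` and column 5 as `score`; the bedGraph value column is stored as
#' `score`.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"bed"`, or `"bedgraph"`.
#' @param oneBased Input coordinates are 1-based closed (default `FALSE`).
#' @param chromAliases Optional named character vector translating the
#'   file's chromosome names (e.g. `c("1" = "chr1")`) — chromosome matching
#'   elsewhere is exact string match.
#' @return A `GRanges`, in file order.
#' @export
readIntervalTrack <- function(path, format = c("auto", "bed", "bedgraph"),
                              oneBased = FALSE, chromAliases = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.(bedgraph|bdg)$", tolower(path))) "bedgraph"
              else "bed"
  }
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) &
                  !grepl("^(track|browser|#)", lines))
  if (length(keep) == 0L) {
    return(GRanges())
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  minCols <- if (format == "bedgraph") 4L else 3L
  bad <- which(nf < minCols)
  if (length(bad)) {
    stop(sprintf("parse error at line %d: expected >= %d tab-separated columns",
                 keep[bad[1L]], minCols), call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  if (!is.null(chromAliases)) {
    hit <- chrom %in% names(chromAliases)
    chrom[hit] <- unname(chromAliases[chrom[hit]])
  }
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(!is.finite(s) | !is.finite(e) | s != round(s) | e != round(e))
  if (length(bad)) {
    stop(sprintf("parse error at line %d: non-numeric coordinates",
                 keep[bad[1L]]), call. = FALSE)
  }
  if (oneBased) {
    s <- s - 1  # convert to 0-based half-open before the shared checks
  }
  bad <- which(s >= e | s < 0)
  if (length(bad)) {
    stop(sprintf("parse error at line %d: start >= end", keep[bad[1L]]),
         call. = FALSE)
  }
  gr <- GRanges(chrom, IRanges(start = s + 1, end = e))
  if (format == "bedgraph") {
    sc <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
    bad <- which(!is.finite(sc))
    if (length(bad)) {
      stop(sprintf("parse error at line %d: non-numeric bedGraph value",
                   keep[bad[1L]]), call. = FALSE)
    }
    mcols(gr)$score <- sc
  } else {
    if (any(nf >= 4L)) {
      mcols(gr)$name <- vapply(fields, function(f)
        if (length(f) >= 4L) f[[4L]] else NA_character_, "")
    }
    if (any(nf >= 5L)) {
      mcols(gr)$score <- suppressWarnings(as.numeric(vapply(fields, function(f)
        if (length(f) >= 5L) f[[5L]] else NA_character_, "")))
    }
  }
  gr
}

#' Write per-bin values as bedGraph
#'
#' Masked bins and `NA` values are omitted. Values survive a round trip
#' through [readIntervalTrack()] + [binTrack()] (`mean_score`) to within
#' 10 significant digits.
#'
#' @param values Numeric vector, one value per bin (full length).
#' @param bins A [GenomeBins].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeBedGraph <- function(values, bins, path) {
  stopifnot(is(bins, "GenomeBins"))
  if (length(values) != nBins(bins)) {
    stop(sprintf(
      "invalid argument: %d values for %d bins", length(values), nBins(bins)
    ), call. = FALSE)
  }
  keep <- !binMask(bins) & !is.na(values)
  br <- binRanges(bins)[keep]
  lines <- sprintf("%s\t%d\t%d\t%s", as.character(seqnames(br)),
                   start(br) - 1L, end(br), .fmtNum(values[keep]))
  writeLines(lines, path)
  invisible(path)
}

#' Write intervals as BED
#'
#' @param gr A [GenomicRanges::GRanges]; `name`/`score` metadata columns, or
#'   the `names`/`scores` arguments, populate BED columns 4-6.
#' @param path Output path.
#' @param names,scores Optional per-interval name and score vectors.
#' @return Invisibly, the path.
#' @export
writeBed <- function(gr, path, names = NULL, scores = NULL) {
  stopifnot(is(gr, "GRanges"))
  if (is.null(names) && "name" %in% base::names(mcols(gr))) {
    names <- mcols(gr)$name
  }
  if (is.null(scores) && "score" %in% base::names(mcols(gr))) {
    scores <- mcols(gr)$score
  }
  o <- order(as.character(seqnames(gr)), start(gr), end(gr))
  gr <- gr[o]
  cols <- list(as.character(seqnames(gr)), start(gr) - 1L, end(gr))
  if (!is.null(names) || !is.null(scores)) {
    cols <- c(cols, list(if (is.null(names)) rep(".", length(gr))
                         else as.character(names)[o]))
  }
  if (!is.null(scores)) {
    cols <- c(cols, list(.fmtNum(as.numeric(scores)[o])))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Write / read a cells-by-bins count table
#'
#' TSV with bin coordinates in the first three columns (`chrom`, `start`,
#' `end`; BED-style 0-based start) followed by one integer column per cell.
#'
#' @param counts Integer matrix, bins x cells, with cell column names.
#' @param bins A [GenomeBins].
#' @param path File path.
#' @return `writeCountsTSV` invisibly returns the path; `readCountsTSV`
#'   returns `list(counts, bins)` where the bins are reconstructed from the
#'   coordinate columns (GC unset, short terminal bins masked).
#' @export
writeCountsTSV <- function(counts, bins, path) {
  stopifnot(is.matrix(counts), nrow(counts) == nBins(bins),
            !is.null(colnames(counts)))
  br <- binRanges(bins)
  df <- data.frame(chrom = as.character(seqnames(br)), start = start(br) - 1L,
                   end = end(br), check.names = FALSE)
  df <- cbind(df, as.data.frame(counts, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCountsTSV
#' @export
readCountsTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  counts <- as.matrix(df[, -(1:3), drop = FALSE])
  storage.mode(counts) <- "integer"
  widths <- df$end - df$start
  binSize <- max(widths)
  lens <- tapply(df$end, df$chrom, max)
  chromOrder <- unique(df$chrom)
  bins <- partitionGenome(setNames(as.numeric(lens[chromOrder]), chromOrder),
                          binSize)
  if (nBins(bins) != nrow(df)) {
    stop("count table bins do not form a contiguous tiling", call. = FALSE)
  }
  list(counts = counts, bins = bins)
}
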