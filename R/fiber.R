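# DNA-fiber arithmetic: track lengths to kb, fork speed, inter-origin
# distances, and grouped summaries.

#' Convert a fiber track length from micrometres to kilobases
#'
#' Stretched DNA fibers carry about 2.59 kb of DNA per micrometre; the
#' conversion is a plain product.
#'
#' @param lengthUm Track length(s) in micrometres (>= 0).
#' @param factorKbPerUm Conversion factor in kb per um (default 2.59).
#' @return Length(s) in kb.
#'
#' @examples
#' umToKb(10)  # 25.9 kb
#' @export
umToKb <- function(lengthUm, factorKbPerUm = 2.59) {
  .checkScalarNum(factorKbPerUm, "factorKbPerUm", lower = 0,
                  strictLower = TRUE)
  if (any(!is.finite(lengthUm) | lengthUm < 0)) {
    stop("invalid argument: lengths must be >= 0", call. = FALSE)
  }
  lengthUm * factorKbPerUm
}

#' Replication fork speed from a labelled track
#'
#' @param trackUm Track length(s) in micrometres.
#' @param pulseMin Label pulse duration in minutes (> 0; default 30).
#' @param factorKbPerUm Conversion factor (default 2.59 kb/um).
#' @return Fork speed(s) in kb/min.
#'
#' @examples
#' forkSpeed(2.9)  # 2.9 * 2.59 / 30 ~ 0.2504 kb/min
#' @export
forkSpeed <- function(trackUm, pulseMin = 30, factorKbPerUm = 2.59) {
  .checkScalarNum(pulseMin, "pulseMin", lower = 0, strictLower = TRUE)
  umToKb(trackUm, factorKbPerUm) / pulseMin
}

#' Inter-origin distances along fibers
#'
#' Adjacent differences of sorted origin midpoint positions per fiber,
#' converted to kb and pooled; fibers with fewer than two origins
#' contribute nothing.
#'
#' @param originPositionsUm Numeric vector of origin positions (one fiber)
#'   or a list of such vectors (many fibers), in micrometres.
#' @param factorKbPerUm Conversion factor (default 2.59 kb/um).
#' @return List with `distancesKb` (pooled) and `medianKb` (`NA` when no
#'   distance exists).
#'
#' @examples
#' interOriginDistances(c(0, 13.127, 26.254))$medianKb  # ~34 kb
#' @export
interOriginDistances <- function(originPositionsUm, factorKbPerUm = 2.59) {
  if (!is.list(originPositionsUm)) {
    originPositionsUm <- list(originPositionsUm)
  }
  d <- unlist(lapply(originPositionsUm, function(p) {
    p <- sort(p[is.finite(p)])
    if (length(p) < 2L) numeric() else diff(p)
  }), use.names = FALSE)
  dk <- umToKb(d, factorKbPerUm)
  list(distancesKb = dk,
       medianKb = if (length(dk)) median(dk) else NA_real_)
}

#' Read a fiber-measurement table
#'
#' TSV with columns `fiber_id`, `group`, `length_um`, optional `pulse_min`,
#' and optional `origin_positions` (semicolon-separated micrometre
#' positions).
#'
#' @param path File path.
#' @return data.frame; `origin_positions` is parsed into a list column
#'   `originPositionsUm`.
#' @export
readFiberMeasurements <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("fiber_id", "group", "length_um")
  if (!all(req %in% names(df))) {
    stop(paste("fiber table needs columns:", paste(req, collapse = ", ")),
         call. = FALSE)
  }
  if ("origin_positions" %in% names(df)) {
    df$originPositionsUm <- lapply(strsplit(df$origin_positions, ";",
                                            fixed = TRUE),
                                   function(x) as.numeric(x[nzchar(x)]))
  }
  df
}

#' Summarize fiber measurements by group
#'
#' Computes the chosen metric per fiber (fork speed) or pooled per group
#' (inter-origin distances), reports per-group medians and sizes, and runs
#' the requested test across groups.
#'
#' @param measurements data.frame as from [readFiberMeasurements()].
#' @param metric `"fork_speed"` or `"inter_origin"`.
#' @param test `"mann_whitney"` (exactly 2 groups) or `"anova"`.
#' @param pulseMin Default pulse duration when the table lacks `pulse_min`.
#' @param factorKbPerUm Conversion factor (default 2.59 kb/um).
#' @return List with `summary` (data.frame: group, n, median) and `test`.
#' @export
summarizeFiberGroups <- function(measurements,
                                 metric = c("fork_speed", "inter_origin"),
                                 test = c("mann_whitney", "anova"),
                                 pulseMin = 30, factorKbPerUm = 2.59) {
  metric <- match.arg(metric)
  test <- match.arg(test)
  stopifnot(is.data.frame(measurements), "group" %in% names(measurements))
  groups <- split(measurements, measurements$group)
  if (length(groups) < 2L) {
    stop("invalid argument: testing requires >= 2 groups", call. = FALSE)
  }
  values <- lapply(groups, function(g) {
    if (metric == "fork_speed") {
      pm <- if ("pulse_min" %in% names(g)) g$pulse_min else pulseMin
      forkSpeed(g$length_um, pm, factorKbPerUm)
    } else {
      if (!"originPositionsUm" %in% names(g)) {
        stop("invalid argument: inter_origin needs origin positions",
             call. = FALSE)
      }
      interOriginDistances(g$originPositionsUm, factorKbPerUm)$distancesKb
    }
  })
  summary <- data.frame(
    group = names(groups),
    n = vapply(values, length, integer(1L)),
    median = vapply(values, function(v)
      if (length(v)) median(v) else NA_real_, numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  testRes <- if (test == "mann_whitney") {
    if (length(values) != 2L) {
      stop("invalid argument: mann_whitney requires exactly 2 groups",
           call. = FALSE)
    }
    mannWhitney(values[[1L]], values[[2L]])
  } else {
    oneWayANOVA(values)
  }
  list(summary = summary, test = testRes, metric = metric)
}

#' Write a fiber group summary as TSV
#'
#' @param summary Result of [summarizeFiberGroups()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeFiberSummary <- function(summary, path) {
  df <- summary$summary
  df$median <- .fmtNum(df$median)
  df$metric <- summary$metric
  df$p_value <- .fmtNum(summary$test$p)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
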