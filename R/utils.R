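# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, restoring the caller's
#' RNG state afterwards so library functions do not perturb user-level
#' random streams.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Length-weighted median; lower weighted median when the mass splits exactly.
weightedMedian <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0))
  ok <- is.finite(x) & w > 0
  x <- x[ok]
  w <- w[ok]
  if (length(x) == 0L) {
    stop("weightedMedian: no usable values", call. = FALSE)
  }
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1L]]
}

# Gaussian kernel smoothing of a regularly spaced series, edge-normalised so
# chromosome ends are not damped.
gaussSmooth <- function(z, len) {
  stopifnot(len >= 1)
  half <- max(1L, ceiling(3 * len))
  k <- stats::dnorm(seq(-half, half), sd = len)
  num <- stats::filter(c(rep(0, half), z, rep(0, half)), k, sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, length(z)), rep(0, half)),
                       k, sides = 2)
  out <- (num / den)[(half + 1L):(half + length(z))]
  as.numeric(out)
}

.checkScalarNum <- function(x, name, lower = -Inf, upper = Inf,
                            strictLower = FALSE, strictUpper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("invalid argument: '%s' must be a finite number", name),
         call. = FALSE)
  }
  if (x < lower || (strictLower && x == lower) ||
      x > upper || (strictUpper && x == upper)) {
    stop(sprintf("invalid argument: '%s' = %s is out of range", name,
                 format(x)), call. = FALSE)
  }
  invisible(x)
}

# Format numbers for text output: stable, locale-free, round-trippable.
.fmtNum <- function(x) {
  out <- sprintf("%.10g", x)
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}
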