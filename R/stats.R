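# Rank and ANOVA tests used by the enrichment and fiber summaries.

#' Mann-Whitney U test
#'
#' U is reported for group `a` (computed from midranks). When both groups
#' have at most `exactMax` observations the null distribution is obtained
#' by full enumeration of the group assignments, with the two-sided p-value
#' counting assignments whose U deviates from its null mean at least as far
#' as observed (enumeration handles ties exactly). Larger samples use the
#' normal approximation with tie correction and a 0.5 continuity
#' correction.
#'
#' @param a,b Numeric value vectors (each non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` (a tends
#'   larger), or `"less"`.
#' @param exactMax Enumeration size limit per group (default 8).
#' @return List with `U`, `p`, `method` ("exact" or "normal"), `nA`, `nB`.
#'
#' @examples
#' mannWhitney(c(1, 2), c(3, 4))  # U = 0, exact two-sided p = 1/3
#' @export
mannWhitney <- function(a, b, alternative = c("two.sided", "greater", "less"),
                        exactMax = 8L) {
  alternative <- match.arg(alternative)
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 1L || length(b) < 1L) {
    stop("invalid argument: both groups must be non-empty", call. = FALSE)
  }
  n1 <- length(a)
  n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  eps <- sqrt(.Machine$double.eps)
  if (n1 <= exactMax && n2 <= exactMax) {
    combs <- combn(n1 + n2, n1)
    cs <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- switch(alternative,
      two.sided = mean(abs(cs - mu) >= abs(U - mu) - eps),
      greater = mean(cs >= U - eps),
      less = mean(cs <= U + eps)
    )
    return(list(U = U, p = p, method = "exact", nA = n1, nB = n2))
  }
  nties <- table(r)
  sigma2 <- (n1 * n2 / 12) *
    ((n1 + n2 + 1) - sum(nties^3 - nties) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sigma2 <= 0) {
    # all values tied: no evidence against the null
    return(list(U = U, p = 1, method = "normal", nA = n1, nB = n2))
  }
  z <- switch(alternative,
    two.sided = (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2),
    greater = (U - mu - 0.5) / sqrt(sigma2),
    less = (U - mu + 0.5) / sqrt(sigma2)
  )
  p <- switch(alternative,
    two.sided = 2 * pnorm(-abs(z)),
    greater = pnorm(z, lower.tail = FALSE),
    less = pnorm(z)
  )
  list(U = U, p = min(p, 1), method = "normal", nA = n1, nB = n2)
}

#' One-way analysis of variance
#'
#' Classical equal-variance F test (between vs within mean squares) via
#' `stats::oneway.test(var.equal = TRUE)`.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 values).
#' @return List with `F`, `p`, `dfBetween`, `dfWithin`.
#' @export
oneWayANOVA <- function(groups) {
  stopifnot(is.list(groups))
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (length(groups) < 2L || any(lengths(groups) < 2L)) {
    stop("invalid argument: need >= 2 groups with >= 2 values each",
         call. = FALSE)
  }
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  grand <- mean(v)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, numeric(1L)) - grand)^2)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1L)))
  df1 <- length(groups) - 1L
  df2 <- length(v) - length(groups)
  if (ssw == 0 && ssb == 0) {
    stop("undefined F: zero between- and within-group variance",
         call. = FALSE)
  }
  if (ssw == 0) {
    return(list(F = Inf, p = 0, dfBetween = df1, dfWithin = df2))
  }
  fit <- stats::oneway.test(v ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), p = unname(fit$p.value),
       dfBetween = df1, dfWithin = df2)
}
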