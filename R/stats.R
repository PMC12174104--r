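#' Wilcoxon signed-rank test with exact small-sample distribution
#'
#' Paired signed-rank test as used for agent comparisons and
#' learning-progress tests. Zero differences are dropped before ranking
#' (Wilcoxon's original rule); ties in \code{|d|} receive midranks. For
#' \code{n <= exactMax} non-zero pairs the p-value is computed from the
#' exact conditional distribution of the positive-rank sum W+ over all
#' \eqn{2^n} sign assignments of the observed midranks (evaluated by
#' dynamic programming, so ties are handled exactly); above that a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y paired numeric vectors; the test is on \code{d = x - y}.
#' @param alternative \code{"two.sided"}, \code{"greater"} (location of
#'   \code{x - y} shifted up) or \code{"less"}.
#' @param exactMax largest n for which the exact distribution is used
#'   (default 25).
#' @return a list with \code{statistic} (W+), \code{p.value}, \code{nUsed}
#'   (pairs after zero-dropping), \code{exact} and \code{alternative}.
#' @examples
#' wilcoxonSignedRank(c(2, 3, 1, 4, 2, 5), rep(0, 6))$p.value  # 2/2^6
#' @export
wilcoxonSignedRank <- function(x, y = NULL,
                               alternative = c("two.sided", "greater", "less"),
                               exactMax = 25L) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  stopifnot(all(is.finite(d)))
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; p = 1")
    return(list(statistic = 0, p.value = 1, nUsed = 0L, exact = TRUE,
                alternative = alternative))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exactMax) {
    # exact conditional distribution over sign assignments; ranks doubled
    # to integers so midranks (x.5) stay exact
    r2 <- as.integer(round(2 * r))
    probs <- .signedRankDistribution(r2)
    w2 <- as.integer(round(2 * w))
    pGreater <- sum(probs[(w2 + 1L):length(probs)])   # P(W >= w)
    pLess <- sum(probs[1:(w2 + 1L)])                  # P(W <= w)
    p <- switch(alternative,
      greater = pGreater,
      less = pLess,
      two.sided = min(1, 2 * min(pGreater, pLess)))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24
    ties <- table(r)
    sig2 <- sig2 - sum(ties^3 - ties) / 48
    z <- function(shift) (w - mu + shift) / sqrt(sig2)
    p <- switch(alternative,
      greater = stats::pnorm(z(-0.5), lower.tail = FALSE),
      less = stats::pnorm(z(0.5)),
      two.sided = min(1, 2 * min(stats::pnorm(z(-0.5), lower.tail = FALSE),
                                 stats::pnorm(z(0.5)))))
    exact <- FALSE
  }
  list(statistic = w, p.value = p, nUsed = n, exact = exact,
       alternative = alternative)
}

# distribution of the signed-rank sum over 2^n equiprobable sign patterns,
# on the doubled-rank (integer) scale: probs[k + 1] = P(2 * W+ == k)
.signedRankDistribution <- function(r2) {
  total <- sum(r2)
  f <- numeric(total + 1L)
  f[1] <- 1
  for (ri in r2) {
    g <- f / 2
    g[(ri + 1L):(total + 1L)] <- g[(ri + 1L):(total + 1L)] +
      f[1:(total + 1L - ri)] / 2
    f <- g
  }
  f
}

#' Compare two agents' paired accuracies
#'
#' Two-sided Wilcoxon signed-rank test on paired per-subject accuracies of
#' two agents (at least 5 pairs).
#'
#' @param accA,accB paired accuracy vectors of equal length >= 5.
#' @return the two-sided p-value.
#' @seealso [wilcoxonSignedRank()]
#' @export
compareAgents <- function(accA, accB) {
  stopifnot(length(accA) == length(accB), length(accA) >= 5)
  wilcoxonSignedRank(accA, accB, alternative = "two.sided")$p.value
}

#' Test for learning progress between session halves
#'
#' One-sided Wilcoxon signed-rank test that the accumulated error count in
#' the second half of training is smaller than in the first half (paired
#' per subject). With n = 9 subjects all improving, the exact p-value is
#' \eqn{1/2^9 \approx 0.00195}.
#'
#' @param errorsFirstHalf,errorsSecondHalf paired per-subject error counts.
#' @return the one-sided p-value for second < first.
#' @export
learningProgress <- function(errorsFirstHalf, errorsSecondHalf) {
  stopifnot(length(errorsFirstHalf) == length(errorsSecondHalf))
  wilcoxonSignedRank(errorsFirstHalf, errorsSecondHalf,
                     alternative = "greater")$p.value
}
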