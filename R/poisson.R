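#' Log-space Poisson upper-tail probability
#'
#' Natural log of \eqn{P(X \ge k)} for \eqn{X \sim Poisson(\lambda)},
#' evaluated through the regularized incomplete gamma function so that
#' probabilities far below double-precision underflow (down to
#' \eqn{p \approx 10^{-300}} and beyond on the log scale) remain accurate.
#' This single primitive backs window eligibility, island significance and
#' the differential-binding test.
#'
#' @param k Non-negative integer observation(s); \code{k <= 0} gives log(1) = 0.
#' @param lambda Positive Poisson mean(s), recycled against \code{k}.
#' @return Numeric vector of natural-log upper-tail probabilities, in
#'   \eqn{(-\infty, 0]}.
#' @examples
#' exp(poissonLogUpperTail(3, 1))      # P(X >= 3 | lambda = 1)
#' poissonLogUpperTail(500, 5) / log(10)  # log10 p, far below underflow
#' @export
poissonLogUpperTail <- function(k, lambda) {
  if (any(lambda < 0)) stop("lambda must be non-negative")
  n <- max(length(k), length(lambda))
  k <- rep_len(as.numeric(k), n)
  lambda <- rep_len(as.numeric(lambda), n)
  out <- numeric(n)
  pos <- k >= 1 & lambda > 0
  # P(X >= k) = P(X > k - 1); pgamma-based, exact in log space
  out[pos] <- stats::ppois(k[pos] - 1, lambda[pos],
                           lower.tail = FALSE, log.p = TRUE)
  # lambda == 0: P(X >= k) = 0 for k >= 1
  out[k >= 1 & lambda == 0] <- -Inf
  out
}

#' Poisson upper-tail probability on the log10 scale
#'
#' @inheritParams poissonLogUpperTail
#' @return \code{log10 P(X >= k)}.
#' @export
poissonLog10UpperTail <- function(k, lambda) {
  poissonLogUpperTail(k, lambda) / log(10)
}

#' Smallest eligible window count at a Poisson background
#'
#' Returns the smallest integer \code{c0} such that
#' \eqn{P(X \ge c0 | \lambda) \le p}. Windows with at least this many
#' fragments are considered enriched-eligible during island calling.
#'
#' @param lambda Background per-window Poisson mean.
#' @param p Eligibility tail probability (default 0.2).
#' @return Integer threshold \code{c0 >= 1}.
#' @export
eligibilityThreshold <- function(lambda, p = 0.2) {
  stopifnot(length(lambda) == 1L, lambda >= 0, p > 0, p < 1)
  if (lambda == 0) return(1L)
  # qpois gives smallest k with P(X <= k) >= 1 - p, i.e. P(X > k) <= p
  k <- stats::qpois(p, lambda, lower.tail = FALSE)
  # threshold on P(X >= c0) = P(X > c0 - 1)
  c0 <- as.integer(k) + 1L
  while (c0 > 1L &&
         poissonLogUpperTail(c0 - 1L, lambda) <= log(p)) c0 <- c0 - 1L
  max(c0, 1L)
}
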