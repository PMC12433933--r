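# Exact beta-binomial pmf/cdf/quantile. All mass computations run in log
# space through lchoose()/lbeta() so that cluster sizes in the tens of
# thousands (micronucleus-test scale, n = 18000) remain stable.

#' Beta mixing shapes from proportion and intraclass correlation
#'
#' \eqn{a = \pi(1-\rho)/\rho}, \eqn{b = (1-\pi)(1-\rho)/\rho}, the
#' parameterisation in which \eqn{\pi = a/(a+b)} is the overall proportion
#' and \eqn{\rho = 1/(1+a+b)} the intraclass correlation.
#'
#' @param pi overall proportion in (0, 1).
#' @param rho intraclass correlation in (0, 1).
#' @return Named list \code{a}, \code{b}.
#' @export
bb_shapes <- function(pi, rho) {
  stopifnot(pi > 0, pi < 1, rho > 0, rho < 1)
  list(a = pi * (1 - rho) / rho, b = (1 - pi) * (1 - rho) / rho)
}

.bb_ab <- function(pi, rho, a, b) {
  if (is.null(a) != is.null(b)) stop("supply both 'a' and 'b' or neither")
  if (is.null(a)) {
    s <- bb_shapes(pi, rho)
    s
  } else {
    stopifnot(a > 0, b > 0)
    list(a = a, b = b)
  }
}

#' Beta-binomial probability mass function
#'
#' \deqn{P(Y = k) = \binom{n}{k}\frac{B(k+a,\,n-k+b)}{B(a,b)}}
#' parameterised either by the beta shapes \code{a}, \code{b} or by the
#' overall proportion \code{pi} and intraclass correlation \code{rho}
#' (see [bb_shapes()]).
#'
#' @param k integer count(s) in \code{0..size}.
#' @param size number of trials.
#' @param pi,rho proportion/intraclass-correlation parameterisation.
#' @param a,b beta shape parameterisation (overrides \code{pi}, \code{rho}).
#' @param log return log probabilities.
#' @return Probability (or log probability) vector.
#' @examples
#' dbetabinom(0:9, size = 9, a = 1, b = 1)  # discrete uniform 1/10
#' @export
dbetabinom <- function(k, size, pi = NULL, rho = NULL, a = NULL, b = NULL,
                       log = FALSE) {
  ab <- .bb_ab(pi, rho, a, b)
  if (any(k < 0) || any(k > size)) stop("'k' must lie in 0..size")
  lp <- lchoose(size, k) + lbeta(k + ab$a, size - k + ab$b) -
    lbeta(ab$a, ab$b)
  if (log) lp else exp(lp)
}

#' Beta-binomial cumulative distribution function
#'
#' @param q integer quantile(s).
#' @inheritParams dbetabinom
#' @return \eqn{P(Y \le q)}.
#' @export
pbetabinom <- function(q, size, pi = NULL, rho = NULL, a = NULL, b = NULL) {
  ab <- .bb_ab(pi, rho, a, b)
  if (any(q < 0) || any(q > size)) stop("'q' must lie in 0..size")
  cdf <- cumsum(dbetabinom(0:max(q), size, a = ab$a, b = ab$b))
  pmin(cdf[q + 1L], 1)
}

#' Beta-binomial quantile function
#'
#' The generalized inverse of the cdf: the smallest integer \code{k} with
#' \eqn{P(Y \le k) \ge p}. The full cdf is evaluated once per call, which
#' stays cheap even at micronucleus-test scale (\code{size = 18000}).
#'
#' @param p probability(ies) in (0, 1).
#' @inheritParams dbetabinom
#' @return Integer quantile vector.
#' @examples
#' qbetabinom(c(0.025, 0.975), size = 18000, pi = 0.1, rho = 0.0027224)
#' @export
qbetabinom <- function(p, size, pi = NULL, rho = NULL, a = NULL, b = NULL) {
  ab <- .bb_ab(pi, rho, a, b)
  if (any(p <= 0) || any(p >= 1)) stop("'p' must lie in (0, 1)")
  cdf <- cumsum(dbetabinom(0:size, size, a = ab$a, b = ab$b))
  # guard against accumulated rounding at the far right tail
  cdf[length(cdf)] <- 1
  # fuzz absorbs cumsum rounding when p hits a cdf value exactly
  vapply(p, function(pp) which(cdf >= pp - 1e-10)[1L] - 1L, integer(1))
}
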