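# Parametric generators for clustered overdispersed binomial counts.
# Below rho_floor the beta mixing collapses numerically (shape parameters
# overflow), so plain binomial sampling is used instead.
.rho_floor <- 1e-12

#' Convert between the dispersion factor and the intraclass correlation
#'
#' Under constant cluster size \code{n} the beta-binomial variance
#' \eqn{n\pi(1-\pi)(1+(n-1)\rho)} and the quasi-binomial variance
#' \eqn{n\pi(1-\pi)\phi} coincide through \eqn{\phi = 1 + (n-1)\rho}.
#' These helpers apply that relation and its exact inverse.
#'
#' @param rho intraclass correlation in \code{[0, 1)}.
#' @param phi dispersion factor in \code{[1, n]}.
#' @param n cluster size (\code{n >= 2}).
#' @return \code{phi_from_rho()} returns \eqn{1 + (n-1)\rho};
#'   \code{rho_from_phi()} returns \eqn{(\phi-1)/(n-1)}.
#' @examples
#' rho_from_phi(50, 18000)   # ~0.00272
#' phi_from_rho(0.010204, 50)
#' @export
phi_from_rho <- function(rho, n) {
  stopifnot(all(n >= 2), all(rho >= 0), all(rho < 1))
  1 + (n - 1) * rho
}

#' @rdname phi_from_rho
#' @export
rho_from_phi <- function(phi, n) {
  stopifnot(all(n >= 2), all(phi >= 1), all(phi <= n))
  (phi - 1) / (n - 1)
}

.check_pi <- function(pi) {
  if (!is.numeric(pi) || length(pi) != 1L || pi <= 0 || pi >= 1) {
    stop("'pi' must be a single value in (0, 1)")
  }
}

#' Sample clustered counts from the beta-binomial model
#'
#' For each cluster \code{h}, draws a success probability
#' \eqn{\pi_h \sim Beta(a, b)} with \eqn{a = \pi(1-\rho)/\rho},
#' \eqn{b = (1-\pi)(1-\rho)/\rho}, then a count
#' \eqn{Y_h \sim Bin(n_h, \pi_h)}. For \code{rho} at (numerical) zero the
#' beta mixing is skipped and plain binomial counts are returned.
#'
#' @param n_vec integer vector of cluster sizes (each \code{>= 1}).
#' @param pi overall event proportion in (0, 1).
#' @param rho intraclass correlation; scalar or one value per cluster.
#' @return Integer vector of counts, one per cluster. Uses R's global
#'   random number stream; call [set.seed()] for reproducibility.
#' @examples
#' set.seed(1)
#' rbetabinom_cluster(rep(50, 10), pi = 0.276, rho = 0.00633)
#' @export
rbetabinom_cluster <- function(n_vec, pi, rho) {
  .check_pi(pi)
  if (any(n_vec < 1)) stop("cluster sizes must be >= 1")
  if (any(rho < 0) || any(rho >= 1)) stop("'rho' must be in [0, 1)")
  k <- length(n_vec)
  if (length(rho) == 1L) rho <- rep(rho, k)
  if (length(rho) != k) stop("'rho' must be scalar or match 'n_vec'")
  p <- rep(pi, k)
  mix <- rho > .rho_floor
  if (any(mix)) {
    a <- pi * (1 - rho[mix]) / rho[mix]
    b <- (1 - pi) * (1 - rho[mix]) / rho[mix]
    p[mix] <- stats::rbeta(sum(mix), a, b)
  }
  stats::rbinom(k, size = n_vec, prob = p)
}

#' Sample clustered counts under the quasi-binomial variance model
#'
#' The quasi-binomial assumption specifies only a variance inflation
#' \eqn{var(Y_h) = n_h\pi(1-\pi)\phi}, not a full distribution. Counts are
#' generated from the beta-binomial distribution whose per-cluster
#' intraclass correlation \eqn{\rho_h = (\phi-1)/(n_h-1)} reproduces that
#' variance exactly; under constant cluster size the two models coincide,
#' so this construction is exact in every balanced design.
#'
#' @inheritParams rbetabinom_cluster
#' @param phi dispersion factor (\code{>= 1}); must satisfy
#'   \code{phi <= n_h} for every cluster.
#' @return Integer vector of counts, one per cluster.
#' @export
rquasibinom_cluster <- function(n_vec, pi, phi) {
  .check_pi(pi)
  if (!is.numeric(phi) || length(phi) != 1L || phi < 1) {
    stop("'phi' must be a single value >= 1")
  }
  if (phi <= 1 + .rho_floor) {
    return(stats::rbinom(length(n_vec), size = n_vec, prob = pi))
  }
  if (any(n_vec < 2)) stop("cluster sizes must be >= 2 when phi > 1")
  if (any(phi > n_vec)) {
    stop("'phi' exceeds a cluster size: implied intraclass correlation >= 1")
  }
  rho_h <- pmin(pmax((phi - 1) / (n_vec - 1), .rho_floor), 1 - 1e-12)
  rbetabinom_cluster(n_vec, pi, rho_h)
}

#' Generate a synthetic historical control data set
#'
#' Draws \code{H} historical control groups of size \code{n} from the
#' beta-binomial model, parameterised either by the intraclass correlation
#' \code{rho} or by the dispersion factor \code{phi} (converted through the
#' constant-cluster-size relation \eqn{\phi = 1+(n-1)\rho}).
#'
#' @param H number of historical groups.
#' @param n cluster size (scalar, or vector of length \code{H}).
#' @param pi overall event proportion.
#' @param rho,phi overdispersion, exactly one of the two.
#' @param seed optional integer seed.
#' @return An [hcd] object.
#' @examples
#' simulate_hcd(H = 10, n = 50, pi = 0.276, phi = 1.31, seed = 1)
#' @export
simulate_hcd <- function(H, n, pi, rho = NULL, phi = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rho) == is.null(phi)) {
    stop("specify exactly one of 'rho' and 'phi'")
  }
  n_vec <- if (length(n) == 1L) rep(n, H) else n
  if (length(n_vec) != H) stop("'n' must be a scalar or of length 'H'")
  y <- if (is.null(phi)) {
    rbetabinom_cluster(n_vec, pi, rho)
  } else {
    rquasibinom_cluster(n_vec, pi, phi)
  }
  hcd(y = y, n = n_vec)
}
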