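# Wald-type prediction intervals. Both variants are built on the pivot
# (n* pi_hat - Y*) / sqrt(var(n* pi_hat) + var(Y*)) ~ approx N(0, 1),
# which treats the plug-in expectation of the future count and the future
# count itself as independent. The uncalibrated intervals use the standard
# normal quantile on both sides; the calibration module replaces it by
# bootstrap-tuned coefficients.

#' Variance components of the quasi-binomial prediction pivot
#'
#' Estimation variance of the scaled pooled proportion and sampling
#' variance of the future count under the quasi-binomial model:
#' \deqn{\widehat{var}(n^*\hat\pi) =
#'   \hat\phi n^{*2} \hat\pi(1-\hat\pi) / \sum_h n_h, \qquad
#'   \widehat{var}(Y^*) = \hat\phi n^* \hat\pi(1-\hat\pi).}
#'
#' @param fit a \code{"qb_fit"} object.
#' @param sum_n total number of historical experimental units
#'   \eqn{\sum_h n_h} (or an [hcd] object, from which it is taken).
#' @param n_star future cluster size.
#' @return Named list \code{var_npi}, \code{var_ystar}.
#' @export
qb_variance <- function(fit, sum_n, n_star) {
  stopifnot(inherits(fit, "qb_fit"))
  if (inherits(sum_n, "hcd")) sum_n <- sum(sum_n$n)
  v <- fit$pi_hat * (1 - fit$pi_hat)
  list(var_npi = fit$phi_hat * n_star^2 * v / sum_n,
       var_ystar = fit$phi_hat * n_star * v)
}

#' Variance components of the beta-binomial prediction pivot
#'
#' \deqn{\widehat{var}(n^*\hat\pi) =
#'   \frac{n^{*2}\hat\pi(1-\hat\pi)}{\sum_h n_h} +
#'   \frac{\sum_h (n_h-1)}{\sum_h n_h} n^{*2}\hat\pi(1-\hat\pi)\hat\rho,
#'   \qquad
#'   \widehat{var}(Y^*) = n^*\hat\pi(1-\hat\pi)(1+(n^*-1)\hat\rho).}
#'
#' @param fit a \code{"bb_fit"} object.
#' @param n_h vector of historical cluster sizes (or an [hcd] object).
#' @param n_star future cluster size.
#' @return Named list \code{var_npi}, \code{var_ystar}.
#' @export
bb_variance <- function(fit, n_h, n_star) {
  stopifnot(inherits(fit, "bb_fit"))
  if (inherits(n_h, "hcd")) n_h <- n_h$n
  v <- fit$pi_hat * (1 - fit$pi_hat)
  sum_n <- sum(n_h)
  list(var_npi = n_star^2 * v / sum_n +
         sum(n_h - 1) / sum_n * n_star^2 * v * fit$rho_hat,
       var_ystar = n_star * v * (1 + (n_star - 1) * fit$rho_hat))
}

.pi_se <- function(fit, n_h, n_star) {
  vv <- if (inherits(fit, "qb_fit")) {
    qb_variance(fit, sum(n_h), n_star)
  } else {
    bb_variance(fit, n_h, n_star)
  }
  sqrt(vv$var_npi + vv$var_ystar)
}

.prediction_interval <- function(expected, se, q_l, q_u, alpha, n_star,
                                 method, calibration = NULL) {
  structure(list(l = expected - q_l * se,
                 u = expected + q_u * se,
                 expected = expected, se = se,
                 q_l = q_l, q_u = q_u,
                 alpha = alpha, n_star = n_star,
                 method = method, calibration = calibration),
            class = "prediction_interval")
}

#' @export
print.prediction_interval <- function(x, ...) {
  cc <- covered_counts(x, x$n_star)
  cat(sprintf("%s %d%% prediction interval for n* = %g:\n",
              x$method, round(100 * (1 - x$alpha)), x$n_star))
  cat(sprintf("  [%.2f, %.2f]  (covered counts %d..%d)\n",
              x$l, x$u, cc[1], cc[2]))
  if (!is.null(x$calibration)) {
    cat(sprintf(
      "  calibrated coefficients q_l = %.4f, q_u = %.4f (B = %d)\n",
      x$q_l, x$q_u, x$calibration$B))
  }
  invisible(x)
}

#' Uncalibrated Wald-type prediction interval
#'
#' The symmetric normal-approximation interval
#' \eqn{n^*\hat\pi \pm z_{1-\alpha/2}
#' \sqrt{\widehat{var}(n^*\hat\pi)+\widehat{var}(Y^*)}} with the variance
#' components of [qb_variance()] or [bb_variance()] according to the class
#' of \code{fit}. Being symmetric and asymptotic, it ignores skewness and
#' tends to undercover for few historical groups; see
#' [calibrate_interval()] for the bootstrap-calibrated version.
#'
#' @param fit a \code{"qb_fit"} or \code{"bb_fit"} object.
#' @param n_h historical cluster sizes (vector or [hcd] object).
#' @param n_star future cluster size.
#' @param alpha nominal two-sided error level.
#' @return A \code{"prediction_interval"} object.
#' @examples
#' wald_interval(qb_fit(0.276, 1.31), n_h = rep(50, 10), n_star = 50)
#' @export
wald_interval <- function(fit, n_h, n_star, alpha = 0.05) {
  if (inherits(n_h, "hcd")) n_h <- n_h$n
  z <- stats::qnorm(1 - alpha / 2)
  method <- if (inherits(fit, "qb_fit")) "quasi-binomial (Wald)"
            else "beta-binomial (Wald)"
  .prediction_interval(n_star * fit$pi_hat, .pi_se(fit, n_h, n_star),
                       z, z, alpha, n_star, method)
}
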