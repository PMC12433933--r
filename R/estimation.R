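# Point estimation of (pi, phi) under the quasi-binomial assumption and of
# (pi, rho) under the beta-binomial model. Apparent underdispersion is
# biologically implausible for clustered toxicological endpoints, so raw
# estimates below the floors are clipped (with a flag), never errors.

#' Dispersion floor for the quasi-binomial fit
#' @noRd
.phi_floor <- 1.001

#' Intraclass-correlation floor for the beta-binomial fit
#' @noRd
.rho_hat_floor <- 0.00001

#' Construct a quasi-binomial fit from known estimates
#'
#' Builds the fit object used by [wald_interval()] and
#' [calibrate_interval()] directly from summary estimates, e.g. values
#' published for a historical control data base when the raw per-study
#' counts are not available.
#'
#' @param pi_hat pooled event proportion in (0, 1).
#' @param phi_hat dispersion factor; clipped to \code{>= 1.001}.
#' @param clipped logical, whether the dispersion estimate was floored.
#' @return An object of class \code{"qb_fit"}.
#' @examples
#' qb_fit(pi_hat = 0.276, phi_hat = 1.31)
#' @export
qb_fit <- function(pi_hat, phi_hat, clipped = phi_hat < .phi_floor) {
  if (pi_hat <= 0 || pi_hat >= 1) stop("degenerate proportion")
  structure(list(pi_hat = pi_hat,
                 phi_hat = max(phi_hat, .phi_floor),
                 clipped = isTRUE(clipped)),
            class = "qb_fit")
}

#' Construct a beta-binomial fit from known estimates
#'
#' @param pi_hat pooled event proportion in (0, 1).
#' @param rho_hat intraclass correlation; clipped to \code{>= 0.00001}.
#' @param clipped logical, whether the correlation estimate was floored.
#' @return An object of class \code{"bb_fit"}.
#' @examples
#' bb_fit(pi_hat = 0.276, rho_hat = 0.00621)
#' @export
bb_fit <- function(pi_hat, rho_hat, clipped = rho_hat < .rho_hat_floor) {
  if (pi_hat <= 0 || pi_hat >= 1) stop("degenerate proportion")
  if (rho_hat >= 1) stop("'rho_hat' must be below 1")
  structure(list(pi_hat = pi_hat,
                 rho_hat = max(rho_hat, .rho_hat_floor),
                 clipped = isTRUE(clipped)),
            class = "bb_fit")
}

#' @export
print.qb_fit <- function(x, ...) {
  cat(sprintf("Quasi-binomial fit: pi_hat = %.4g, phi_hat = %.4g%s\n",
              x$pi_hat, x$phi_hat,
              if (x$clipped) " (dispersion floored at 1.001)" else ""))
  invisible(x)
}

#' @export
print.bb_fit <- function(x, ...) {
  cat(sprintf("Beta-binomial fit: pi_hat = %.4g, rho_hat = %.4g%s\n",
              x$pi_hat, x$rho_hat,
              if (x$clipped) " (ICC floored at 1e-05)" else ""))
  invisible(x)
}

#' Quasi-binomial estimation for historical control data
#'
#' Fits the intercept-only quasi-likelihood model: the pooled proportion
#' \eqn{\hat\pi = \sum_h y_h / \sum_h n_h} and the Pearson dispersion
#' estimate
#' \deqn{\hat\phi = \frac{1}{H-1}\sum_h
#'   \frac{(y_h - n_h\hat\pi)^2}{n_h\hat\pi(1-\hat\pi)},}
#' the same estimates an intercept-only \code{glm(..., quasibinomial)}
#' reports. \eqn{\hat\phi} is clipped to \code{>= 1.001} since
#' underdispersion of clustered binary endpoints is implausible. The
#' all-zero adjustment ([adjust_all_zero()]) is applied first.
#'
#' @param data an [hcd] object.
#' @param adjust apply the all-zero adjustment first (default TRUE).
#' @return An object of class \code{"qb_fit"} with elements \code{pi_hat},
#'   \code{phi_hat} and \code{clipped}.
#' @examples
#' fit_quasibinomial(hcd(y = c(5, 15), n = c(50, 50)))
#' @export
fit_quasibinomial <- function(data, adjust = TRUE) {
  stopifnot(inherits(data, "hcd"))
  if (adjust) data <- adjust_all_zero(data)
  y <- data$y; n <- data$n; H <- length(y)
  pi_hat <- sum(y) / sum(n)
  if (pi_hat <= 0 || pi_hat >= 1) stop("degenerate proportion")
  pearson <- sum((y - n * pi_hat)^2 / (n * pi_hat * (1 - pi_hat)))
  phi_raw <- pearson / (H - 1)
  qb_fit(pi_hat, phi_raw, clipped = phi_raw < .phi_floor)
}

#' Beta-binomial estimation for historical control data
#'
#' The pooled proportion as in [fit_quasibinomial()], and the
#' analysis-of-variance moment estimator of the intraclass correlation for
#' clustered binary data:
#' \deqn{\hat\rho = \frac{BMS - WMS}{BMS + (n_0-1) WMS}}
#' with \eqn{p_h = y_h/n_h},
#' \eqn{BMS = \sum_h n_h (p_h - \hat\pi)^2 / (H-1)},
#' \eqn{WMS = \sum_h n_h p_h (1-p_h) / \sum_h (n_h - 1)} and
#' \eqn{n_0 = (\sum_h n_h - \sum_h n_h^2 / \sum_h n_h)/(H-1)}.
#' \eqn{\hat\rho} is clipped to \code{>= 0.00001}. The all-zero adjustment
#' is applied first.
#'
#' @inheritParams fit_quasibinomial
#' @return An object of class \code{"bb_fit"} with elements \code{pi_hat},
#'   \code{rho_hat} and \code{clipped}.
#' @examples
#' fit_betabinomial(hcd(y = c(5, 15), n = c(50, 50)))
#' @export
fit_betabinomial <- function(data, adjust = TRUE) {
  stopifnot(inherits(data, "hcd"))
  if (adjust) data <- adjust_all_zero(data)
  y <- data$y; n <- data$n; H <- length(y)
  pi_hat <- sum(y) / sum(n)
  if (pi_hat <= 0 || pi_hat >= 1) stop("degenerate proportion")
  p <- y / n
  bms <- sum(n * (p - pi_hat)^2) / (H - 1)
  wms <- sum(n * p * (1 - p)) / sum(n - 1)
  n0 <- (sum(n) - sum(n^2) / sum(n)) / (H - 1)
  rho_raw <- if (bms == 0 && wms == 0) {
    -Inf  # degenerate: no within- or between-cluster variation
  } else {
    (bms - wms) / (bms + (n0 - 1) * wms)
  }
  # upper guard: WMS = 0 with BMS > 0 yields exactly 1, outside (0, 1)
  rho_raw <- min(rho_raw, 1 - 1e-8)
  bb_fit(pi_hat, max(rho_raw, .rho_hat_floor),
         clipped = rho_raw < .rho_hat_floor)
}
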