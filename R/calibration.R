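# Parametric-bootstrap calibration of the Wald-type prediction intervals.
#
# The normal quantile in the Wald interval is replaced, separately for each
# limit, by a coefficient q tuned so that the bootstrap-estimated per-side
# coverage hits 1 - alpha/2 within a tolerance t. One ensemble of B
# (historical data set, future count) pairs is drawn once from the fitted
# model and reused for every q evaluation and for both sides; only q
# varies during the bisection.
#
# Bootstrap re-estimation intentionally differs from the initial fit in
# one point: the Pearson dispersion of a replicate is used raw (it is
# non-negative by construction), NOT floored at 1.001. The floor exists to
# rule out implausible underdispersion in the reported estimate; applying
# it inside the bootstrap would clamp the majority of replicates' standard
# errors for small H and shrink the pivot distribution whose spread the
# calibration is meant to propagate. The ANOVA intraclass-correlation
# estimate, by contrast, keeps its floor in the refits because a negative
# value can drive the plug-in variance to (or below) zero, leaving the
# pivot undefined.

#' Parametric bootstrap ensemble for interval calibration
#'
#' Draws \code{B} bootstrap pairs from the fitted model: a historical data
#' set with the original design \code{n_h} and one future count of size
#' \code{n_star}. Each bootstrap historical set is re-estimated with the
#' same pipeline as the original fit (all-zero adjustment; the intraclass
#' correlation floored at 1e-05, the Pearson dispersion used raw — see the
#' package vignette for why the refits are not floored at 1.001), and the
#' plug-in expected future count
#' \eqn{n^*\hat\pi_b} and prediction standard error
#' \eqn{\sqrt{\widehat{var}_b(n^*\hat\pi)+\widehat{var}_b(Y^*)}} are
#' recorded.
#'
#' Re-estimation is vectorised across replicates using the closed forms of
#' [fit_quasibinomial()] / [fit_betabinomial()]; the rare all-zero (or
#' all-event) replicates are adjusted exactly as the scalar pipeline does.
#'
#' @param fit a \code{"qb_fit"} or \code{"bb_fit"} object; the sampling
#'   model matches its class.
#' @param n_h historical cluster sizes (vector or [hcd] object).
#' @param n_star future cluster size.
#' @param B number of bootstrap pairs.
#' @return A \code{"bootstrap_ensemble"}: list with numeric vectors
#'   \code{expected}, \code{se} and integer vector \code{ystar}, each of
#'   length \code{B}.
#' @export
bootstrap_ensemble <- function(fit, n_h, n_star, B = 10000) {
  if (inherits(n_h, "hcd")) n_h <- n_h$n
  H <- length(n_h)
  if (H < 2) stop("at least 2 historical groups required")
  pi <- fit$pi_hat
  model <- if (inherits(fit, "qb_fit")) "qb"
           else if (inherits(fit, "bb_fit")) "bb"
           else stop("'fit' must be a qb_fit or bb_fit object")

  if (model == "qb") {
    if (any(fit$phi_hat > n_h) || fit$phi_hat > n_star) {
      stop("'phi_hat' exceeds a cluster size: cannot sample")
    }
    rho_h <- pmin(pmax((fit$phi_hat - 1) / (n_h - 1), .rho_floor), 1 - 1e-12)
    rho_star <- pmin(pmax((fit$phi_hat - 1) / (n_star - 1), .rho_floor),
                     1 - 1e-12)
  } else {
    rho_h <- rep(fit$rho_hat, H)
    rho_star <- fit$rho_hat
  }

  # B bootstrap historical sets, one per column
  Y <- matrix(rbetabinom_cluster(rep(n_h, B), pi, rep(rho_h, B)), nrow = H)
  ystar <- rbetabinom_cluster(rep(n_star, B), pi, rho_star)

  ytot <- colSums(Y)
  sum_n <- sum(n_h)
  # all-zero / all-event replicates need the half-unit adjustment before
  # re-estimation; handled per replicate through the scalar pipeline
  degen <- which(ytot == 0 | ytot == sum_n)

  pi_b <- ytot / sum_n
  if (model == "qb") {
    ok <- pi_b > 0 & pi_b < 1
    phi_b <- rep(1e-10, B)
    if (any(ok)) {
      denom <- outer(n_h, pi_b[ok] * (1 - pi_b[ok]))
      resid2 <- (Y[, ok, drop = FALSE] - outer(n_h, pi_b[ok]))^2
      # raw Pearson/df; epsilon guard keeps the SE positive when all
      # replicate clusters happen to coincide
      phi_b[ok] <- pmax(colSums(resid2 / denom) / (H - 1), 1e-10)
    }
    v <- pi_b * (1 - pi_b)
    var_npi <- phi_b * n_star^2 * v / sum_n
    var_ystar <- phi_b * n_star * v
  } else {
    p_hb <- Y / n_h
    bms <- colSums(n_h * sweep(p_hb, 2, pi_b)^2) / (H - 1)
    wms <- colSums(n_h * p_hb * (1 - p_hb)) / sum(n_h - 1)
    n0 <- (sum_n - sum(n_h^2) / sum_n) / (H - 1)
    rho_b <- ifelse(bms == 0 & wms == 0, .rho_hat_floor,
                    (bms - wms) / (bms + (n0 - 1) * wms))
    rho_b <- pmin(pmax(rho_b, .rho_hat_floor), 1 - 1e-8)
    v <- pi_b * (1 - pi_b)
    var_npi <- n_star^2 * v / sum_n +
      sum(n_h - 1) / sum_n * n_star^2 * v * rho_b
    var_ystar <- n_star * v * (1 + (n_star - 1) * rho_b)
  }
  expected <- n_star * pi_b
  se <- sqrt(var_npi + var_ystar)

  for (b in degen) {
    d <- adjust_all_zero(hcd(Y[, b], n_h))
    sum_nd <- sum(d$n)
    pi_d <- sum(d$y) / sum_nd
    v_d <- pi_d * (1 - pi_d)
    if (model == "qb") {
      phi_d <- max(sum((d$y - d$n * pi_d)^2 / (d$n * v_d)) / (H - 1), 1e-10)
      se[b] <- sqrt(phi_d * n_star^2 * v_d / sum_nd + phi_d * n_star * v_d)
    } else {
      f_b <- fit_betabinomial(d, adjust = FALSE)
      se[b] <- sqrt(sum(unlist(bb_variance(f_b, d$n, n_star))))
      pi_d <- f_b$pi_hat
    }
    expected[b] <- n_star * pi_d
  }

  structure(list(expected = expected, se = se, ystar = ystar,
                 B = B, model = model, n_star = n_star),
            class = "bootstrap_ensemble")
}

#' Bootstrap coverage of a one-sided limit at coefficient q
#'
#' For the lower side, the fraction of bootstrap pairs with
#' \eqn{l_b = E_b - q \cdot se_b \le y^*_b}; for the upper side, the
#' fraction with \eqn{y^*_b \le u_b = E_b + q \cdot se_b}. All replicates
#' share the same \code{q}, so the function is a non-decreasing step
#' function of \code{q} with jumps of \code{1/B}.
#'
#' @param q non-negative quantile coefficient.
#' @param ensemble a \code{"bootstrap_ensemble"}.
#' @param side \code{"lower"} or \code{"upper"}.
#' @return Estimated per-side coverage in \code{[0, 1]}.
#' @export
coverage_at <- function(q, ensemble, side = c("lower", "upper")) {
  side <- match.arg(side)
  if (q < 0) stop("'q' must be non-negative")
  with(ensemble, if (side == "lower") {
    mean(expected - q * se <= ystar)
  } else {
    mean(ystar <= expected + q * se)
  })
}

#' Bisection search for a calibrated quantile coefficient
#'
#' Finds \code{q} such that the bootstrap per-side coverage
#' [coverage_at()] lies within \code{target +/- t} (inclusive), where
#' \code{target = 1 - alpha/2}. The initial bracket \code{(0, q_max)} is
#' expanded geometrically (doubling, up to 5 times) if it does not yet
#' contain the target. Because the empirical coverage is a step function
#' with jumps of \code{1/B}, a tolerance below \code{1/(2B)} may be
#' unattainable; in that case the jump point whose coverage is closest to
#' the target from above is returned (conservative direction).
#'
#' @param ensemble a \code{"bootstrap_ensemble"}.
#' @param side \code{"lower"} or \code{"upper"}.
#' @param alpha nominal two-sided error level; the per-side target is
#'   \code{1 - alpha/2}.
#' @param t tolerance around the target coverage.
#' @param q_max initial upper bracket endpoint.
#' @param max_iter maximum bisection iterations.
#' @return The calibrated coefficient, with the achieved coverage in
#'   attribute \code{"coverage"}.
#' @export
bisect_q <- function(ensemble, side = c("lower", "upper"), alpha = 0.05,
                     t = 0.001, q_max = 20, max_iter = 200) {
  side <- match.arg(side)
  target <- 1 - alpha / 2
  lo <- 0
  cov_lo <- coverage_at(lo, ensemble, side)
  if (cov_lo >= target) {
    # already saturated at the smallest admissible coefficient
    return(structure(lo, coverage = cov_lo))
  }
  hi <- q_max
  cov_hi <- coverage_at(hi, ensemble, side)
  expansions <- 0L
  while (cov_hi < target && expansions < 5L) {
    hi <- hi * 2
    cov_hi <- coverage_at(hi, ensemble, side)
    expansions <- expansions + 1L
  }
  if (cov_hi < target) {
    stop("bisection bracket does not contain the target coverage")
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    cov_mid <- coverage_at(mid, ensemble, side)
    if (abs(cov_mid - target) <= t) {
      return(structure(mid, coverage = cov_mid))
    }
    if (cov_mid < target) {
      lo <- mid
    } else {
      hi <- mid
      cov_hi <- cov_mid
    }
    if (hi - lo < 1e-10) break
  }
  # tolerance band unattainable on the 1/B grid: return the jump point
  # covering from above
  structure(hi, coverage = cov_hi)
}

#' Bootstrap-calibrated prediction interval
#'
#' Calibrates the Wald-type interval of [wald_interval()] by the
#' parametric-bootstrap procedure: (1) draw \code{B} bootstrap historical
#' sets and future counts from the fitted model, (2) re-estimate the model
#' per replicate, (3) find, independently for each limit, the quantile
#' coefficient whose bootstrap per-side coverage is \eqn{1-\alpha/2} within
#' tolerance \code{t} (bisection), and (4) apply the calibrated
#' coefficients with the ORIGINAL fit's expected value and standard error:
#' \deqn{l = n^*\hat\pi - q_l^{calib} \cdot se, \qquad
#'       u = n^*\hat\pi + q_u^{calib} \cdot se.}
#' Both limits are calibrated on the same ensemble, so skewness of the
#' fitted distribution yields asymmetric coefficients (equal-tail
#' behaviour).
#'
#' @param fit a \code{"qb_fit"} or \code{"bb_fit"} object, from
#'   [fit_quasibinomial()] / [fit_betabinomial()] or constructed from
#'   published estimates via [qb_fit()] / [bb_fit()].
#' @param n_h historical cluster sizes (vector or [hcd] object).
#' @param n_star future cluster size.
#' @param alpha nominal two-sided error level.
#' @param B number of bootstrap pairs.
#' @param t bisection tolerance on the per-side coverage.
#' @param side \code{"both"} for a two-sided interval; \code{"lower"} or
#'   \code{"upper"} calibrate a single bound at target \code{1 - alpha}.
#' @param seed optional integer seed for the bootstrap.
#' @return A \code{"prediction_interval"} whose \code{calibration} element
#'   records \code{q_l}, \code{q_u}, achieved bootstrap coverages
#'   \code{psi_l}, \code{psi_u}, \code{B}, \code{t} and \code{seed}.
#' @examples
#' calibrate_interval(qb_fit(0.276, 1.31), n_h = rep(50, 10), n_star = 50,
#'                    B = 2000, seed = 1)
#' @export
calibrate_interval <- function(fit, n_h, n_star, alpha = 0.05, B = 10000,
                               t = 0.001, side = c("both", "lower", "upper"),
                               seed = NULL) {
  side <- match.arg(side)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(n_h, "hcd")) n_h <- n_h$n
  ens <- bootstrap_ensemble(fit, n_h, n_star, B)
  alpha_side <- if (side == "both") alpha else 2 * alpha
  q_l <- q_u <- 0
  psi_l <- psi_u <- NA_real_
  if (side %in% c("both", "lower")) {
    q_l <- bisect_q(ens, "lower", alpha_side, t)
    psi_l <- attr(q_l, "coverage")
  }
  if (side %in% c("both", "upper")) {
    q_u <- bisect_q(ens, "upper", alpha_side, t)
    psi_u <- attr(q_u, "coverage")
  }
  calib <- list(q_l = as.numeric(q_l), q_u = as.numeric(q_u),
                psi_l = psi_l, psi_u = psi_u,
                B = B, t = t, seed = seed, side = side)
  method <- if (ens$model == "qb") "quasi-binomial (calibrated)"
            else "beta-binomial (calibrated)"
  pi_obj <- .prediction_interval(n_star * fit$pi_hat,
                                 .pi_se(fit, n_h, n_star),
                                 as.numeric(q_l), as.numeric(q_u),
                                 alpha, n_star, method, calib)
  if (side == "lower") pi_obj$u <- Inf
  if (side == "upper") pi_obj$l <- -Inf
  pi_obj
}

#' Prediction interval for a future control group
#'
#' One-stop interface: fits the requested overdispersion model to the
#' historical control data and returns the bootstrap-calibrated (default)
#' or uncalibrated Wald-type prediction interval for a future control
#' group of size \code{n_star}.
#'
#' @param data an [hcd] object.
#' @param n_star future cluster size.
#' @param model \code{"qb"} (quasi-binomial) or \code{"bb"}
#'   (beta-binomial).
#' @param alpha nominal two-sided error level.
#' @param calibrate use bootstrap calibration (default) or the plain
#'   Wald interval.
#' @param B,t,seed passed to [calibrate_interval()].
#' @return A \code{"prediction_interval"} object.
#' @examples
#' d <- simulate_hcd(H = 10, n = 50, pi = 0.276, phi = 1.31, seed = 7)
#' prediction_interval(d, n_star = 50, model = "qb", B = 2000, seed = 1)
#' @export
prediction_interval <- function(data, n_star, model = c("qb", "bb"),
                                alpha = 0.05, calibrate = TRUE, B = 10000,
                                t = 0.001, seed = NULL) {
  model <- match.arg(model)
  fit <- if (model == "qb") fit_quasibinomial(data) else fit_betabinomial(data)
  if (calibrate) {
    calibrate_interval(fit, data$n, n_star, alpha, B, t, seed = seed)
  } else {
    wald_interval(fit, data$n, n_star, alpha)
  }
}
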