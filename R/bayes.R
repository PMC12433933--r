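# Bayesian posterior-predictive prediction intervals, fitted by MCMC
# through JAGS (rjags). Two models:
#   * hierarchical beta-binomial: pi_h ~ Beta(mu*kappa, (1-mu)*kappa) with
#     mu ~ Uniform(0,1) and a gamma prior on the precision kappa;
#   * logit-link binomial GLMM: logit(pi_h) = nu + beta_h,
#     beta_h ~ N(0, sigma), with vague priors on nu and sigma.
# The Bayesian path never applies the all-zero adjustment: zero counts are
# handled natively by the likelihood.
#
# JAGS is a Gibbs/slice sampler, so the HMC notion of divergent
# transitions does not apply; convergence is monitored through the
# split-chain potential scale reduction factor (R-hat) across chains.

.hier_model_string <- "
model {
  for (h in 1:H) {
    y[h] ~ dbin(p[h], n[h])
    p[h] ~ dbeta(mu * kappa, (1 - mu) * kappa)
  }
  mu ~ dunif(0, 1)
  kappa ~ dgamma(kappa_shape, kappa_rate)
}"

# centred parameterisation (eta_h ~ N(nu, sigma)) mixes much better under
# Gibbs sampling than the offset form nu + beta_h; beta_h is derived
.glmm_model_string <- "
model {
  for (h in 1:H) {
    y[h] ~ dbin(p[h], n[h])
    logit(p[h]) <- eta[h]
    eta[h] ~ dnorm(nu, tau)
    beta[h] <- eta[h] - nu
  }
  nu ~ dnorm(0, pow(nu_sd, -2))
  sigma ~ dt(0, pow(sigma_scale, -2), 1) T(0,)
  tau <- pow(sigma, -2)
}"

.check_bayes_data <- function(data) {
  stopifnot(inherits(data, "hcd"))
  if (any(data$y != round(data$y)) || any(data$n != round(data$n))) {
    stop("Bayesian models require integer counts and cluster sizes")
  }
  list(y = as.integer(round(data$y)), n = as.integer(round(data$n)),
       H = nrow(data))
}

.run_jags <- function(model_string, jags_data, variables, C, chains,
                      warmup, adapt, seed, model_label, extra = list()) {
  iter_per_chain <- ceiling(C / chains)
  if (is.null(warmup)) warmup <- iter_per_chain
  inits <- NULL
  if (!is.null(seed)) {
    inits <- lapply(seq_len(chains), function(i) {
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = as.integer((seed + 1000L * i) %% .Machine$integer.max))
    })
  }
  fit <- tryCatch({
    jm <- rjags::jags.model(textConnection(model_string), data = jags_data,
                            n.chains = chains, n.adapt = adapt,
                            inits = inits, quiet = TRUE)
    stats::update(jm, n.iter = warmup, progress.bar = "none")
    samp <- rjags::coda.samples(jm, variable.names = variables,
                                n.iter = iter_per_chain,
                                progress.bar = "none")
    rhat <- tryCatch(
      coda::gelman.diag(samp, autoburnin = FALSE,
                        multivariate = FALSE)$psrf[, 1L],
      error = function(e) {
        r <- rep(NA_real_, coda::nvar(samp))
        names(r) <- coda::varnames(samp)
        r
      })
    draws <- as.matrix(samp)
    if (nrow(draws) > C) draws <- draws[seq_len(C), , drop = FALSE]
    list(draws = draws, rhat = rhat, error = NULL)
  }, error = function(e) list(draws = NULL, rhat = NULL,
                              error = conditionMessage(e)))
  converged <- is.null(fit$error) && all(is.finite(fit$rhat)) &&
    all(fit$rhat < 1.05)
  structure(c(list(model = model_label, C = C, chains = chains,
                   warmup = warmup, seed = seed, converged = converged),
              fit, extra),
            class = "bayes_fit")
}

#' @export
print.bayes_fit <- function(x, ...) {
  cat(sprintf("Bayesian %s fit: %d retained draws, %d chains\n",
              x$model, if (is.null(x$draws)) 0L else nrow(x$draws),
              x$chains))
  if (!is.null(x$error)) {
    cat("  sampler error:", x$error, "\n")
  } else {
    cat(sprintf("  max R-hat = %.3f; converged: %s\n",
                max(x$rhat, na.rm = TRUE), x$converged))
  }
  invisible(x)
}

#' Fit the Bayesian hierarchical beta-binomial model
#'
#' Mean-precision beta prior on the per-study proportions,
#' \eqn{\pi_h \sim Beta(\mu\kappa, (1-\mu)\kappa)}, with
#' \eqn{\mu \sim Uniform(0,1)} and a weakly informative gamma prior
#' \eqn{\kappa \sim Ga(a, b)} on the precision. The default
#' \code{Ga(2, 5e-5)} places the precision in the large domain appropriate
#' for weakly overdispersed large-cluster data; it needs case-by-case
#' adaptation — e.g. \code{kappa_rate = 5e-3} for small-cluster mortality
#' data — and a poorly matched prior is a known source of convergence
#' failure of this model.
#'
#' @param data an [hcd] object with integer counts.
#' @param C total number of retained posterior draws (across chains).
#' @param chains number of MCMC chains.
#' @param kappa_shape,kappa_rate gamma prior on the precision
#'   \eqn{\kappa}.
#' @param warmup burn-in iterations per chain (default: retained
#'   iterations per chain).
#' @param adapt JAGS adaptation iterations.
#' @param seed optional integer seed (per-chain RNG seeds derived from it).
#' @return A \code{"bayes_fit"} object with a draws matrix (columns
#'   \code{mu}, \code{kappa}), per-parameter R-hat, and a \code{converged}
#'   flag. Sampler failures are captured in the \code{error} element, not
#'   raised.
#' @export
fit_bayes_hier <- function(data, C = 5000, chains = 4, kappa_shape = 2,
                           kappa_rate = 5e-5, warmup = NULL, adapt = 1000,
                           seed = NULL) {
  d <- .check_bayes_data(data)
  .run_jags(.hier_model_string,
            list(y = d$y, n = d$n, H = d$H,
                 kappa_shape = kappa_shape, kappa_rate = kappa_rate),
            c("mu", "kappa"), C, chains, warmup, adapt, seed, "hierarchical",
            extra = list(kappa_shape = kappa_shape, kappa_rate = kappa_rate))
}

#' Fit the Bayesian logit-link binomial GLMM
#'
#' Random-intercept model \eqn{logit(\pi_h) = \nu + \beta_h},
#' \eqn{\beta_h \sim N(0, \sigma)}, with a wide normal prior on the
#' intercept (\code{sd = nu_sd}) and a half-Cauchy prior with scale
#' \code{sigma_scale} on the between-study standard deviation. Because
#' \eqn{\sigma} is a positive scale parameter, its posterior stays above
#' zero even for homogeneous data, which makes the resulting predictive
#' intervals mildly conservative in the absence of overdispersion.
#'
#' @inheritParams fit_bayes_hier
#' @param nu_sd prior standard deviation of the intercept.
#' @param sigma_scale half-Cauchy prior scale of the random-effect SD.
#' @return A \code{"bayes_fit"} object with draws of \code{nu},
#'   \code{sigma} and the study effects \code{beta[h]}.
#' @export
fit_bayes_glmm <- function(data, C = 5000, chains = 4, nu_sd = 10,
                           sigma_scale = 2.5, warmup = NULL, adapt = 1000,
                           seed = NULL) {
  d <- .check_bayes_data(data)
  .run_jags(.glmm_model_string,
            list(y = d$y, n = d$n, H = d$H,
                 nu_sd = nu_sd, sigma_scale = sigma_scale),
            c("nu", "sigma", "beta"), C, chains, warmup, adapt, seed, "glmm",
            extra = list(nu_sd = nu_sd, sigma_scale = sigma_scale))
}

.check_predictable <- function(fit) {
  if (is.null(fit$draws)) {
    stop("cannot predict from a failed fit: ", fit$error)
  }
}

#' Posterior-predictive draws of a future control-group count
#'
#' For each retained posterior draw, simulates the future study's success
#' proportion and then the future count: under the hierarchical model
#' \eqn{\pi^*_c \sim Beta(\mu_c\kappa_c, (1-\mu_c)\kappa_c)}; under the
#' GLMM a new random intercept \eqn{\beta^*_c \sim N(0, \sigma_c)},
#' \eqn{\pi^*_c = logit^{-1}(\nu_c + \beta^*_c)}. In both cases
#' \eqn{y^*_c \sim Bin(n^*, \pi^*_c)}.
#'
#' @param fit a \code{"bayes_fit"} object.
#' @param n_star future cluster size.
#' @return A \code{"posterior_predictive"} object: list with integer
#'   \code{draws} (length \code{C}, values in \code{0..n_star}),
#'   \code{n_star}, and the fit's convergence diagnostics.
#' @export
posterior_predict <- function(fit, n_star) {
  stopifnot(inherits(fit, "bayes_fit"))
  .check_predictable(fit)
  C <- nrow(fit$draws)
  p_star <- if (fit$model == "hierarchical") {
    mu <- fit$draws[, "mu"]; kappa <- fit$draws[, "kappa"]
    stats::rbeta(C, mu * kappa, (1 - mu) * kappa)
  } else {
    nu <- fit$draws[, "nu"]; sigma <- fit$draws[, "sigma"]
    stats::plogis(nu + stats::rnorm(C, 0, sigma))
  }
  draws <- stats::rbinom(C, size = n_star, prob = p_star)
  structure(list(draws = draws, n_star = n_star, model = fit$model,
                 converged = fit$converged, rhat = fit$rhat),
            class = "posterior_predictive")
}

#' Prediction interval from posterior-predictive draws
#'
#' Empirical \eqn{\alpha/2} and \eqn{1-\alpha/2} quantiles of the
#' predictive draws. Two quantile rules are exposed because the draws are
#' discrete counts: \code{"interpolation"} (R's default type-7 quantile,
#' which can return fractional limits such as 21.025) and
#' \code{"nearest_rank"} (type 1, always an observed count).
#'
#' @param pp a \code{"posterior_predictive"} object, or a numeric vector
#'   of predictive draws.
#' @param alpha nominal two-sided error level.
#' @param type quantile rule.
#' @param n_star future cluster size (taken from \code{pp} if available).
#' @return A \code{"prediction_interval"} object.
#' @export
predictive_interval <- function(pp, alpha = 0.05,
                                type = c("interpolation", "nearest_rank"),
                                n_star = NULL) {
  type <- match.arg(type)
  draws <- if (inherits(pp, "posterior_predictive")) pp$draws else pp
  if (length(draws) < 100L) stop("at least 100 predictive draws required")
  if (is.null(n_star)) {
    n_star <- if (inherits(pp, "posterior_predictive")) pp$n_star
              else max(draws)
  }
  qtype <- if (type == "interpolation") 7L else 1L
  lu <- stats::quantile(draws, c(alpha / 2, 1 - alpha / 2), type = qtype,
                        names = FALSE)
  method <- if (inherits(pp, "posterior_predictive")) {
    paste0("Bayesian ", pp$model)
  } else "posterior predictive"
  structure(list(l = lu[1], u = lu[2],
                 expected = mean(draws), se = stats::sd(draws),
                 q_l = NA_real_, q_u = NA_real_,
                 alpha = alpha, n_star = n_star, method = method,
                 calibration = NULL,
                 converged = if (inherits(pp, "posterior_predictive"))
                   pp$converged else NA),
            class = "prediction_interval")
}

#' Bayesian prediction interval for a future control group
#'
#' Convenience wrapper: fits the requested Bayesian model, draws the
#' posterior predictive distribution of the future count, and returns its
#' equal-tail interval. If the sampler fails or R-hat exceeds 1.05 the
#' function stops unless \code{force = TRUE}, in which case the (suspect)
#' interval is returned with its \code{converged} flag set to
#' \code{FALSE}.
#'
#' @param data an [hcd] object.
#' @param n_star future cluster size.
#' @param model \code{"hierarchical"} or \code{"glmm"}.
#' @param alpha nominal two-sided error level.
#' @param C total retained MCMC draws.
#' @param seed optional integer seed (drives both the MCMC chains and the
#'   predictive sampling).
#' @param force return an interval even when convergence is in doubt.
#' @param type quantile rule, see [predictive_interval()].
#' @param ... further arguments to [fit_bayes_hier()] /
#'   [fit_bayes_glmm()] (priors, chains, warmup).
#' @return A \code{"prediction_interval"} object.
#' @export
bayes_interval <- function(data, n_star, model = c("glmm", "hierarchical"),
                           alpha = 0.05, C = 5000, seed = NULL,
                           force = FALSE,
                           type = c("interpolation", "nearest_rank"), ...) {
  model <- match.arg(model)
  fit <- if (model == "hierarchical") {
    fit_bayes_hier(data, C = C, seed = seed, ...)
  } else {
    fit_bayes_glmm(data, C = C, seed = seed, ...)
  }
  if (!fit$converged && !force) {
    stop(sprintf(
      "Bayesian %s model did not converge (%s); rerun with adapted priors or force = TRUE",
      model,
      if (!is.null(fit$error)) fit$error
      else sprintf("max R-hat = %.3f", max(fit$rhat, na.rm = TRUE))))
  }
  if (!is.null(seed)) set.seed(seed + 1L)
  predictive_interval(posterior_predict(fit, n_star), alpha, type)
}
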