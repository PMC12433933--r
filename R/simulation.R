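# Monte-Carlo engine for coverage-probability studies of historical
# control limits: repeatedly draw a historical data set plus one future
# count from the beta-binomial generator, compute each method's limits,
# and summarise two-sided and per-side coverage and average limits.

#' Define a simulation setting
#'
#' A single cell of a coverage study: the data-generating parameters, the
#' number of simulation runs, and the limit methods to evaluate. Cluster
#' sizes are constant (\code{n_h = n_star} for all groups), the design
#' under which the quasi-binomial and beta-binomial variance models
#' coincide through \eqn{\phi = 1+(n-1)\rho}.
#'
#' @param H number of historical groups per run.
#' @param pi overall event proportion.
#' @param phi dispersion factor (the intraclass correlation is derived as
#'   \eqn{(\phi-1)/(n-1)}).
#' @param n historical (and future) cluster size.
#' @param n_star future cluster size; must equal \code{n}.
#' @param S number of simulation runs.
#' @param B bootstrap pairs per calibrated interval.
#' @param C retained MCMC draws per Bayesian interval.
#' @param alpha nominal two-sided error level.
#' @param methods character vector among \code{"range"}, \code{"np"},
#'   \code{"meansd"}, \code{"qb"}, \code{"bb"} (calibrated),
#'   \code{"qb_uncal"}, \code{"bb_uncal"}, \code{"bayes_glmm"},
#'   \code{"bayes_hier"}, \code{"oracle"} (the true beta-binomial
#'   quantiles, a benchmark that always covers at least nominally).
#' @return A \code{"sim_setting"} list.
#' @export
sim_setting <- function(H, pi, phi, n, n_star = n, S = 500, B = 2000,
                        C = 1000, alpha = 0.05,
                        methods = c("range", "np", "meansd", "qb", "bb")) {
  if (n_star != n) {
    stop("the engine assumes constant cluster size: n_star must equal n")
  }
  known <- c("range", "np", "meansd", "qb", "bb", "qb_uncal", "bb_uncal",
             "bayes_glmm", "bayes_hier", "oracle")
  bad <- setdiff(methods, known)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  structure(list(H = H, pi = pi, phi = phi, n = n, n_star = n_star,
                 S = S, B = B, C = C, alpha = alpha, methods = methods),
            class = "sim_setting")
}

.method_limits <- function(method, data, setting, rho) {
  alpha <- setting$alpha
  n_star <- setting$n_star
  lim <- switch(method,
    range = historical_range(data),
    np = np_chart(data, n_star, k = 2),
    meansd = mean_k_sd(data, k = 2),
    qb = calibrate_interval(fit_quasibinomial(data, adjust = FALSE),
                            data$n, n_star, alpha, B = setting$B),
    bb = calibrate_interval(fit_betabinomial(data, adjust = FALSE),
                            data$n, n_star, alpha, B = setting$B),
    qb_uncal = wald_interval(fit_quasibinomial(data, adjust = FALSE),
                             data$n, n_star, alpha),
    bb_uncal = wald_interval(fit_betabinomial(data, adjust = FALSE),
                             data$n, n_star, alpha),
    bayes_glmm = bayes_interval(data, n_star, "glmm", alpha,
                                C = setting$C),
    bayes_hier = bayes_interval(data, n_star, "hierarchical", alpha,
                                C = setting$C),
    oracle = {
      q <- qbetabinom(c(alpha / 2, 1 - alpha / 2), n_star,
                      pi = setting$pi, rho = max(rho, 1e-12))
      list(l = q[1], u = q[2])
    })
  c(lim$l, lim$u)
}

#' Run one simulation setting
#'
#' Draws \code{S} historical data sets and matching single future counts
#' from the beta-binomial generator, applies the all-zero adjustment for
#' the frequentist pipeline, computes every requested method's limits, and
#' summarises the two-sided coverage \eqn{\psi_{cp}}, the per-side
#' coverages \eqn{\psi_l = P(l \le y^*)} and \eqn{\psi_u = P(y^* \le u)},
#' and the average limits over successful runs. Method failures (errors,
#' or non-convergence of a Bayesian fit) are counted and excluded from the
#' coverage denominators, never silently dropped.
#'
#' The historical/future data stream is generated before any method runs,
#' so adding or removing methods does not perturb it; each method receives
#' its own derived random substream.
#'
#' @param setting a [sim_setting()].
#' @param seed integer master seed.
#' @return A data frame with one row per method: the setting parameters,
#'   \code{psi_cp}, \code{psi_l}, \code{psi_u}, \code{l_bar}, \code{u_bar},
#'   \code{failures} and the effective number of runs \code{S_used}.
#' @examples
#' run_setting(sim_setting(H = 10, pi = 0.3, phi = 3, n = 50, S = 50),
#'             seed = 1)
#' @export
run_setting <- function(setting, seed = NULL) {
  stopifnot(inherits(setting, "sim_setting"))
  if (!is.null(seed)) set.seed(seed)
  S <- setting$S; H <- setting$H
  rho <- rho_from_phi(setting$phi, setting$n)
  rho_gen <- max(rho, 0)  # phi = 1 maps to the plain binomial
  Y <- matrix(rbetabinom_cluster(rep(setting$n, H * S), setting$pi, rho_gen),
              nrow = H)
  ystar <- rbetabinom_cluster(rep(setting$n_star, S), setting$pi, rho_gen)
  method_seeds <- sample.int(.Machine$integer.max - 1L,
                             length(setting$methods))

  n_vec <- rep(setting$n, H)
  rows <- lapply(seq_along(setting$methods), function(m) {
    method <- setting$methods[m]
    lims <- matrix(NA_real_, nrow = S, ncol = 2)
    for (s in seq_len(S)) {
      set.seed((method_seeds[m] + s) %% .Machine$integer.max)
      d <- adjust_all_zero(hcd(Y[, s], n_vec))
      lims[s, ] <- tryCatch(
        suppressWarnings(.method_limits(method, d, setting, rho)),
        error = function(e) c(NA_real_, NA_real_))
    }
    ok <- !is.na(lims[, 1])
    cover_l <- lims[ok, 1] <= ystar[ok]
    cover_u <- ystar[ok] <= lims[ok, 2]
    data.frame(method = method, H = H, pi = setting$pi, phi = setting$phi,
               n = setting$n, n_star = setting$n_star, S = S,
               S_used = sum(ok),
               psi_cp = mean(cover_l & cover_u),
               psi_l = mean(cover_l), psi_u = mean(cover_u),
               l_bar = mean(lims[ok, 1]), u_bar = mean(lims[ok, 2]),
               failures = sum(!ok))
  })
  do.call(rbind, rows)
}

#' Run a list of simulation settings
#'
#' @param settings list of [sim_setting()] objects (e.g. from
#'   [mnt_grid()] or [ltc_grid()]).
#' @param seed master seed; each setting receives a derived seed.
#' @return Row-bound data frame of [run_setting()] results.
#' @export
run_grid <- function(settings, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  setting_seeds <- sample.int(.Machine$integer.max - 1L, length(settings))
  do.call(rbind, lapply(seq_along(settings), function(i) {
    run_setting(settings[[i]], seed = setting_seeds[i])
  }))
}

#' Factorial simulation grid inspired by the in vitro micronucleus test
#'
#' Large standardised clusters (18,000 scored cells), small proportions,
#' and potentially very large overdispersion: the full factorial of
#' \code{H} in \{5, 10, 20, 100\}, \code{pi} in \{0.001, 0.01, 0.1\} and
#' \code{phi} in \{1.001, 3, 5, 10, 50, 500\} — 72 settings.
#'
#' @param ... overrides passed to every [sim_setting()] (e.g. \code{S},
#'   \code{B}, \code{methods}).
#' @return List of 72 [sim_setting()] objects.
#' @export
mnt_grid <- function(...) {
  g <- expand.grid(H = c(5, 10, 20, 100), pi = c(0.001, 0.01, 0.1),
                   phi = c(1.001, 3, 5, 10, 50, 500))
  lapply(seq_len(nrow(g)), function(i) {
    sim_setting(H = g$H[i], pi = g$pi[i], phi = g$phi[i], n = 18000, ...)
  })
}

#' Factorial simulation grid inspired by long-term carcinogenicity studies
#'
#' Rodent-bioassay scale: clusters of 50 animals, moderate proportions and
#' overdispersion: the full factorial of \code{H} in \{5, 10, 20, 100\},
#' \code{pi} in \{0.01, 0.1, 0.2, 0.3, 0.4, 0.5\} and \code{phi} in
#' \{1.001, 1.5, 3, 5\} — 96 settings.
#'
#' @inheritParams mnt_grid
#' @return List of 96 [sim_setting()] objects.
#' @export
ltc_grid <- function(...) {
  g <- expand.grid(H = c(5, 10, 20, 100),
                   pi = c(0.01, 0.1, 0.2, 0.3, 0.4, 0.5),
                   phi = c(1.001, 1.5, 3, 5))
  lapply(seq_len(nrow(g)), function(i) {
    sim_setting(H = g$H[i], pi = g$pi[i], phi = g$phi[i], n = 50, ...)
  })
}
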