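test_that("predictive quantiles follow the chosen empirical rule", {
  draws <- 0:99
  ci <- predictive_interval(draws, alpha = 0.05, type = "interpolation")
  expect_equal(c(ci$l, ci$u), c(2.475, 96.525))
  ci1 <- predictive_interval(draws, alpha = 0.05, type = "nearest_rank")
  expect_equal(c(ci1$l, ci1$u), c(2, 97))
  flat <- predictive_interval(rep(7, 200))
  expect_equal(flat$l, flat$u)
  expect_error(predictive_interval(1:50), "at least 100")
})

test_that("predictive interval matches binomial quantiles on binomial draws", {
  set.seed(14)
  draws <- rbinom(20000, 50, 0.5)
  ci <- predictive_interval(draws, alpha = 0.05, type = "nearest_rank",
                            n_star = 50)
  expect_lte(abs(ci$l - qbinom(0.025, 50, 0.5)), 1)
  expect_lte(abs(ci$u - qbinom(0.975, 50, 0.5)), 1)
})

fake_fit <- function(draws, model) {
  structure(list(draws = draws, model = model, converged = TRUE,
                 rhat = setNames(rep(1, ncol(draws)), colnames(draws)),
                 error = NULL, chains = 1L),
            class = "bayes_fit")
}

test_that("posterior prediction reduces to the binomial in the no-heterogeneity limit", {
  # GLMM with sigma = 0 and nu = 0: pi* = 1/2 exactly
  set.seed(21)
  C <- 20000
  g <- fake_fit(cbind(nu = rep(0, C), sigma = rep(0, C)), "glmm")
  ppg <- posterior_predict(g, n_star = 50)
  expect_true(all(ppg$draws >= 0 & ppg$draws <= 50))
  expect_equal(mean(ppg$draws), 25, tolerance = 3 * sqrt(12.5 / C) / 25)

  # hierarchical with huge precision: Beta(mu*kappa, .) degenerates at mu
  h <- fake_fit(cbind(mu = rep(0.5, C), kappa = rep(1e9, C)),
                "hierarchical")
  pph <- posterior_predict(h, n_star = 50)
  expect_equal(mean(pph$draws), 25, tolerance = 3 * sqrt(12.5 / C) / 25)
  expect_equal(var(pph$draws), 12.5, tolerance = 0.15)

  # the two no-heterogeneity limits agree within Monte-Carlo error
  expect_equal(mean(ppg$draws), mean(pph$draws),
               tolerance = 7 * sqrt(12.5 / C) / 25)

  # empty future cluster
  expect_true(all(posterior_predict(h, n_star = 0)$draws == 0))
})

test_that("hierarchical fit is seeded, sized, and robust to all-zero data", {
  d <- simulate_hcd(H = 10, n = 50, pi = 0.3, rho = 0.01, seed = 6)
  f1 <- fit_bayes_hier(d, C = 800, chains = 2, adapt = 300,
                       kappa_rate = 5e-3, seed = 7)
  f2 <- fit_bayes_hier(d, C = 800, chains = 2, adapt = 300,
                       kappa_rate = 5e-3, seed = 7)
  expect_s3_class(f1, "bayes_fit")
  expect_identical(f1$draws, f2$draws)
  expect_equal(nrow(f1$draws), 800L)
  expect_true(all(c("mu", "kappa") %in% colnames(f1$draws)))
  expect_true(is.finite(max(f1$rhat)))

  # all-zero data: the contract is "completes or flags", never an error
  z <- hcd(rep(0, 5), rep(50, 5))
  expect_no_error(fz <- fit_bayes_hier(z, C = 400, chains = 2, adapt = 200,
                                       seed = 3))
  expect_type(fz$converged, "logical")

  # fractional counts are a frequentist device only
  expect_error(fit_bayes_hier(hcd(c(0.5, 1), c(49.5, 50))), "integer")
})

test_that("GLMM fit recovers the intercept on synthetic data", {
  set.seed(33)
  nu_true <- qlogis(0.3)
  d <- simulate_hcd(H = 30, n = 200, pi = 0.3, rho = 0.012, seed = 34)
  f <- fit_bayes_glmm(d, C = 1200, chains = 2, adapt = 400, seed = 35)
  expect_true(f$converged)
  nu_draws <- f$draws[, "nu"]
  expect_lt(abs(mean(nu_draws) - nu_true), 3 * sd(nu_draws))
  # positive scale parameter: never collapses to zero exactly
  expect_true(all(f$draws[, "sigma"] > 0))
})

test_that("end-to-end Bayesian interval is reproducible and plausible", {
  d <- mortality_like_hcd()
  ci <- bayes_interval(d, n_star = 50, model = "glmm", C = 1200, seed = 44,
                       chains = 2, adapt = 400)
  ci2 <- bayes_interval(d, n_star = 50, model = "glmm", C = 1200, seed = 44,
                        chains = 2, adapt = 400)
  expect_identical(c(ci$l, ci$u), c(ci2$l, ci2$u))
  # slightly conservative limits around the mortality-like data: the
  # interval should enclose the plain binomial central region
  expect_lte(ci$l, qbinom(0.025, 50, sum(d$y) / sum(d$n)))
  expect_gte(ci$u, qbinom(0.975, 50, sum(d$y) / sum(d$n)))
  expect_true(ci$l >= 0 && ci$u <= 50)
})
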