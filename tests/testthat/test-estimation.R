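test_that("quasi-binomial fit matches hand-evaluated Pearson dispersion", {
  f <- fit_quasibinomial(hcd(c(5, 15), c(50, 50)))
  expect_equal(f$pi_hat, 0.2)
  # Pearson residuals: (5-10)^2/8 + (15-10)^2/8 = 6.25 on 1 df
  expect_equal(f$phi_hat, 6.25, tolerance = 1e-12)
  expect_false(f$clipped)

  # identical clusters: zero between-cluster variation, floored at 1.001
  g <- fit_quasibinomial(hcd(c(10, 10), c(50, 50)))
  expect_equal(g$pi_hat, 0.2)
  expect_equal(g$phi_hat, 1.001)
  expect_true(g$clipped)
})

test_that("quasi-binomial fit agrees with the glm quasi-likelihood fit", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- rep(50, 8)
    y <- rbetabinom_cluster(n, pi = 0.3, rho = 0.08)
    f <- fit_quasibinomial(hcd(y, n))
    glm_fit <- stats::glm(cbind(y, n - y) ~ 1, family = stats::quasibinomial())
    expect_equal(f$pi_hat, unname(stats::plogis(stats::coef(glm_fit))),
                 tolerance = 1e-9)
    if (!f$clipped) {
      # glm evaluates the Pearson statistic at its IRLS-converged mean,
      # numerically (not exactly) the pooled proportion
      expect_equal(f$phi_hat, summary(glm_fit)$dispersion, tolerance = 1e-5)
    }
  }
})

test_that("beta-binomial fit matches the hand-evaluated ANOVA estimator", {
  f <- fit_betabinomial(hcd(c(5, 15), c(50, 50)))
  expect_equal(f$pi_hat, 0.2)
  # BMS = 1, WMS = 15/98, n0 = 50 -> rho = 83/833
  expect_equal(f$rho_hat, 83 / 833, tolerance = 1e-12)

  g <- fit_betabinomial(hcd(c(10, 10), c(50, 50)))
  expect_equal(g$rho_hat, 1e-5)
  expect_true(g$clipped)
})

test_that("both estimators pool the proportion identically", {
  set.seed(3)
  for (i in 1:5) {
    n <- sample(30:80, 12, replace = TRUE)
    y <- rbetabinom_cluster(n, 0.25, 0.05)
    d <- hcd(y, n)
    expect_identical(fit_quasibinomial(d)$pi_hat, fit_betabinomial(d)$pi_hat)
  }
})

test_that("estimators recover generator parameters on synthetic data", {
  set.seed(91)
  # balanced design, moderate ICC
  rho_hats <- replicate(60, {
    d <- simulate_hcd(H = 100, n = 50, pi = 0.3, rho = 0.05)
    fit_betabinomial(d)$rho_hat
  })
  expect_equal(mean(rho_hats), 0.05, tolerance = 0.1)

  phi_hats <- replicate(60, {
    d <- simulate_hcd(H = 10, n = 50, pi = 0.276, phi = 1.31)
    fit_quasibinomial(d)$phi_hat
  })
  expect_equal(mean(phi_hats), 1.31, tolerance = 0.15)
})

test_that("phi and rho estimates target the same dispersion at large H", {
  set.seed(17)
  d <- simulate_hcd(H = 1000, n = 50, pi = 0.3, rho = 0.06)
  phi_hat <- fit_quasibinomial(d)$phi_hat
  rho_hat <- fit_betabinomial(d)$rho_hat
  expect_equal(phi_from_rho(rho_hat, 50) / phi_hat, 1, tolerance = 0.05)
})

test_that("degenerate proportions are adjusted or rejected", {
  all0 <- hcd(c(0, 0, 0), c(50, 50, 50))
  f <- fit_quasibinomial(all0)  # auto all-zero adjustment
  expect_equal(f$pi_hat, 0.5 / 149.5)
  expect_error(fit_quasibinomial(all0, adjust = FALSE),
               "degenerate proportion")
  expect_error(fit_betabinomial(all0, adjust = FALSE),
               "degenerate proportion")
})
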