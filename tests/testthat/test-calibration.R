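# A hand-built ensemble small enough to enumerate the coverage indicator
# by brute force.
toy_ensemble <- function() {
  structure(list(expected = rep(10, 5), se = rep(1, 5),
                 ystar = c(8, 9, 10, 11, 12), B = 5L),
            class = "bootstrap_ensemble")
}

test_that("coverage_at counts the limit indicators exactly", {
  ens <- toy_ensemble()
  # lower limits 10 - 1.5 = 8.5: covers y* in {9,10,11,12}
  expect_equal(coverage_at(1.5, ens, "lower"), 4 / 5)
  expect_equal(coverage_at(1.5, ens, "upper"), 4 / 5)
  # q = 0: the median split, up to discreteness (10 <= y* for 3 of 5)
  expect_equal(coverage_at(0, ens, "lower"), 3 / 5)
  expect_equal(coverage_at(0, ens, "upper"), 3 / 5)
  # saturation
  expect_equal(coverage_at(50, ens, "lower"), 1)
  expect_error(coverage_at(-1, ens, "lower"), "non-negative")
})

test_that("coverage_at is monotone non-decreasing in q", {
  set.seed(5)
  ens <- structure(list(expected = rnorm(500, 10), se = runif(500, 0.5, 2),
                        ystar = rpois(500, 10)),
                   class = "bootstrap_ensemble")
  for (side in c("lower", "upper")) {
    cov <- sapply(seq(0, 5, by = 0.25), coverage_at, ensemble = ens,
                  side = side)
    expect_true(all(diff(cov) >= 0))
  }
})

test_that("bisection lands in the attainable coverage band", {
  ens <- toy_ensemble()
  # per-side target 0.8 (alpha = 0.4): pivots (10 - y*)/se = 2,1,0,-1,-2,
  # so any q in [1, 2) covers exactly 4 of 5
  q <- bisect_q(ens, "lower", alpha = 0.4, t = 0.001)
  expect_gte(as.numeric(q), 1)
  expect_lt(as.numeric(q), 2)
  expect_equal(attr(q, "coverage"), 0.8)

  # degenerate ensemble: q = 0 already saturates
  flat <- structure(list(expected = rep(10, 5), se = rep(1, 5),
                         ystar = rep(10, 5)),
                    class = "bootstrap_ensemble")
  q0 <- bisect_q(flat, "lower", alpha = 0.05)
  expect_equal(as.numeric(q0), 0)
  expect_equal(attr(q0, "coverage"), 1)
})

test_that("bisection recovers the normal quantile on standard-normal pivots", {
  set.seed(101)
  ens <- structure(list(expected = rep(0, 10000), se = rep(1, 10000),
                        ystar = rnorm(10000)),
                   class = "bootstrap_ensemble")
  q_l <- bisect_q(ens, "lower", alpha = 0.05, t = 0.001)
  q_u <- bisect_q(ens, "upper", alpha = 0.05, t = 0.001)
  expect_equal(as.numeric(q_l), qnorm(0.975), tolerance = 0.05)
  expect_equal(as.numeric(q_u), qnorm(0.975), tolerance = 0.05)
})

test_that("bootstrap ensemble honours its contracts", {
  fit <- qb_fit(0.276, 1.31)
  set.seed(1)
  e1 <- bootstrap_ensemble(fit, rep(50, 10), 50, B = 1)
  expect_length(e1$expected, 1L)
  expect_length(e1$ystar, 1L)

  set.seed(2)
  ens <- bootstrap_ensemble(fit, rep(50, 10), 50, B = 4000)
  expect_true(all(ens$se > 0))
  expect_true(all(ens$ystar == round(ens$ystar)))
  # pooled proportion is unbiased under the generator
  expect_equal(mean(ens$expected), 13.8,
               tolerance = 3 * sd(ens$expected) / sqrt(4000) / 13.8)

  # dispersion at the floor with huge historical information:
  # standard errors concentrate near the binomial future-sampling SD
  set.seed(3)
  tight <- bootstrap_ensemble(qb_fit(0.276, 1.001), rep(50, 2000), 50,
                              B = 500)
  expect_equal(mean(tight$se), sqrt(50 * 0.276 * 0.724), tolerance = 0.05)
})

test_that("calibrated intervals are reproducible and bracket the estimate", {
  fit <- bb_fit(0.3, 0.02)
  a <- calibrate_interval(fit, rep(50, 10), 50, B = 2000, seed = 42)
  b <- calibrate_interval(fit, rep(50, 10), 50, B = 2000, seed = 42)
  expect_identical(a[c("l", "u", "q_l", "q_u")], b[c("l", "u", "q_l", "q_u")])
  expect_lte(a$l, a$expected)
  expect_gte(a$u, a$expected)
  # achieved bootstrap coverages sit in the tolerance band
  expect_equal(a$calibration$psi_l, 0.975, tolerance = 0.002)
  expect_equal(a$calibration$psi_u, 0.975, tolerance = 0.002)
})

test_that("skewed settings calibrate the two limits asymmetrically", {
  # right-skewed: small proportion, strong overdispersion, small clusters
  fit <- bb_fit(0.05, 0.1)
  ci <- calibrate_interval(fit, rep(50, 10), 50, B = 4000, seed = 9)
  expect_false(isTRUE(all.equal(ci$q_l, ci$q_u, tolerance = 0.01)))
})

test_that("one-sided calibration targets 1 - alpha on a single bound", {
  fit <- qb_fit(0.276, 1.31)
  up <- calibrate_interval(fit, rep(50, 10), 50, alpha = 0.05, B = 4000,
                           side = "upper", seed = 5)
  expect_identical(up$l, -Inf)
  expect_equal(up$calibration$psi_u, 0.95, tolerance = 0.002)
})

test_that("with ample data the calibrated interval approaches the exact binomial quantiles", {
  # dispersion at its floor and a very large historical base: the fitted
  # predictive distribution is essentially Binomial(n*, pi)
  fit <- qb_fit(0.276, 1.001)
  ci <- calibrate_interval(fit, rep(50, 2000), 50, B = 10000, seed = 31)
  expect_lt(abs(ci$l - qbinom(0.025, 50, 0.276)), 1)
  expect_lt(abs(ci$u - qbinom(0.975, 50, 0.276)), 1)
})

test_that("end-to-end interface fits, calibrates and tags the method", {
  d <- mortality_like_hcd()
  ci <- prediction_interval(d, n_star = 50, model = "qb", B = 1000, seed = 2)
  expect_s3_class(ci, "prediction_interval")
  expect_match(ci$method, "calibrated")
  expect_equal(ci$expected, 50 * sum(d$y) / sum(d$n))
  w <- prediction_interval(d, n_star = 50, model = "bb", calibrate = FALSE)
  expect_match(w$method, "Wald")
})
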