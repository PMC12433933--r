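---
title: "Historical control limits for overdispersed binomial endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Historical control limits for overdispersed binomial endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hclimits)
```

## The problem

Toxicological test guidelines (OECD 471/473/487/490 and related) require
the concurrent control group of a study to be validated against historical
control data (HCD): control-group outcomes of previous studies of the same
design. The validation instrument is a pair of historical control limits
(HCL) $[l, u]$ that should cover the upcoming control outcome $y^*$ with a
stated confidence,
$$P(l \le y^* \le u) = 1 - \alpha,$$
usually $1-\alpha = 0.95$. For dichotomous endpoints the data are
clustered counts: $y_h$ animals with a tumour out of $n_h = 50$ in a
long-term carcinogenicity (LTC) study, or $y_h$ micronucleated cells out
of $n_h = 18{,}000$ scored cells in the in vitro micronucleus test (MNT).

Because the $H$ historical control groups come from different studies,
their event proportions vary systematically. The counts are then
*overdispersed*: their variance exceeds the binomial $n\pi(1-\pi)$. Two
standard variance models capture this:

* **beta-binomial**: $\pi_h \sim Beta(a, b)$, $Y_h \sim Bin(n_h, \pi_h)$,
  with overall proportion $\pi = a/(a+b)$, intraclass correlation
  $\rho = 1/(1+a+b)$ and variance
  $n_h\pi(1-\pi)\,(1 + (n_h-1)\rho)$;
* **quasi-binomial**: a constant inflation $var(Y_h) = n_h\pi(1-\pi)\phi$,
  $\phi \ge 1$.

Under constant cluster size the two coincide through
$\phi = 1 + (n-1)\rho$ ([phi_from_rho()], [rho_from_phi()]). Negative
intraclass correlation — apparent *under*dispersion — is biologically
implausible for these endpoints (one tumour does not protect the cage
mates), so estimates are restricted from below (see *Estimation*).

A valid HCL must also respect **equal tail probabilities**,
$P(l \le y^*) = P(y^* \le u) = 1 - \alpha/2$: each limit should cut off
exactly $\alpha/2$ of the predictive distribution even when that
distribution is skewed, as it is for small $\pi$, strong overdispersion,
or small clusters.

## Why the routine heuristics fail

The package implements the three heuristics of daily practice as
comparators — [historical_range()], [np_chart()] (limits
$n^*\bar\pi \pm k\sqrt{n^*\bar\pi(1-\bar\pi)}$) and [mean_k_sd()]
($\bar y \pm k\,SD$) — and the Monte-Carlo engine reproduces their known
failure modes (see `tests/testthat/test-acceptance.R`):

* the historical range targets *all* observable values, so its coverage
  drifts towards 1 as $H$ grows: no error control;
* the np-chart ignores overdispersion and estimation uncertainty; its
  coverage collapses far below 0.6 once $\phi \gtrsim 10$;
* mean $\pm$ 2 SD allows for overdispersion heuristically but is
  symmetric, so it cannot deliver equal tails under skewness.

## The calibrated prediction intervals

Both frequentist intervals build on the approximate pivot
$$\frac{n^*\hat\pi - Y^*}{\sqrt{\widehat{var}(n^*\hat\pi) +
\widehat{var}(Y^*)}} \sim N(0, 1),$$
with plug-in variances (see [qb_variance()], [bb_variance()]) under the
chosen model. The plain Wald interval [wald_interval()] is symmetric and
asymptotic; it undercovers for small $H$ and ignores skewness.

[calibrate_interval()] therefore replaces the normal quantile by
coefficients $q_l^{calib}, q_u^{calib}$ tuned by a parametric bootstrap:

1. fit the model to the HCD (after the all-zero adjustment, below);
2. draw $B$ bootstrap historical data sets with the original design and
   $B$ future counts of size $n^*$ from the fitted model;
3. re-estimate the model on each bootstrap data set, giving per-replicate
   expected values and standard errors;
4. for each side separately, bisect on $q$ until the bootstrap fraction of
   covered future counts is $1 - \alpha/2$ within tolerance $t$;
5. apply $q_l^{calib}, q_u^{calib}$ with the *original* fit's expected
   value and standard error.

All replicates share one ensemble; only $q$ moves during bisection, so
the per-side coverage is a monotone step function with jumps of $1/B$ and
bisection is valid. Skewness of the fitted distribution shows up as
$q_l^{calib} \ne q_u^{calib}$, which is how the interval achieves equal
tails.

### Defaults and numerical choices

* $\alpha = 0.05$, $B = 10{,}000$, tolerance $t = 0.001$; these are the
  study conditions under which the method is characterised.
* Bisection bracket $(0, 20)$, doubled up to 5 times if the target
  coverage lies outside; at most 200 iterations; the band test is
  inclusive. When $t < 1/(2B)$ the band can fall between two jumps of the
  empirical step function; the jump covering from above is returned
  (conservative direction).
* **All-zero adjustment**: if every $y_h = 0$, the first group is set to
  $y_1 = 0.5$ with $n_1$ reduced by $0.5$, so the frequentist estimates
  stay positive; it is applied automatically by the frequentist pipeline
  (never by the Bayesian one) and generalises the published $n = 50$ rule
  to any cluster size. The mirrored rule handles the all-events case,
  which keeps bootstrap re-estimation defined at extreme proportions.
* **Estimation floors**: the *reported* estimates are restricted to
  $\hat\phi \ge 1.001$ and $\hat\rho \ge 10^{-5}$, since underdispersion
  is implausible. Inside the bootstrap, however, the Pearson dispersion of
  a replicate is used *raw*: it is non-negative by construction, and
  flooring it at 1.001 would clamp the majority of replicates when
  $H = 10$ ($P(\chi^2_9/9 < 1.001) \approx 0.56$), shrinking exactly the
  pivot spread the calibration is supposed to propagate; with the floor,
  the worked mortality example below is irreproducible. The ANOVA
  intraclass-correlation estimate keeps its floor in the refits because a
  negative value can push the plug-in variance to zero or below, leaving
  the pivot undefined. This asymmetry is deliberate.

### Estimation

Both models share the pooled proportion
$\hat\pi = \sum_h y_h / \sum_h n_h$ (the intercept-only quasi-likelihood
fit). The dispersion estimates are the Pearson statistic over $H-1$
degrees of freedom ([fit_quasibinomial()], identical to
`glm(..., quasibinomial)`'s dispersion, which the test suite cross-checks)
and the analysis-of-variance moment estimator of the intraclass
correlation for clustered binary data ([fit_betabinomial()]). Closed forms
are used rather than a `glm()` call because the bootstrap refits them
$10^4$ times per interval.

## Bayesian intervals

Two posterior-predictive intervals complement the frequentist ones, both
sampled with JAGS ([fit_bayes_hier()], [fit_bayes_glmm()],
[posterior_predict()], [predictive_interval()]):

* a **hierarchical beta-binomial** model in mean–precision form,
  $\pi_h \sim Beta(\mu\kappa, (1-\mu)\kappa)$, $\mu \sim U(0,1)$,
  $\kappa \sim Ga(a, b)$. The default $Ga(2, 5\cdot10^{-5})$ targets the
  weak-overdispersion/large-cluster domain; it *must* be adapted case by
  case (e.g. rate $5\cdot10^{-3}$ for 50-animal clusters), and a
  mismatched prior is the model's characteristic convergence failure —
  which the package surfaces via the `converged` flag rather than hiding;
* a **logit-link random-intercept GLMM**,
  $logit(\pi_h) = \nu + \beta_h$, $\beta_h \sim N(0, \sigma)$, with a wide
  normal prior on $\nu$ (sd 10) and a half-Cauchy prior (scale 2.5) on
  $\sigma$; both hyperparameters are configurable since "vague" admits a
  family of choices. Internally the centred parameterisation
  $\eta_h \sim N(\nu, \sigma)$ is sampled — it mixes far better under
  Gibbs sampling than the offset form. Because $\sigma > 0$ by
  construction, the GLMM is mildly conservative when heterogeneity is
  absent.

Defaults: 4 chains, $C = 5000$ retained draws in total, warm-up equal to
the retained iterations per chain. Convergence is judged by split-chain
R-hat $< 1.05$ across 4 chains; JAGS is a Gibbs/slice sampler, so
divergent-transition counts (an HMC diagnostic) do not exist here.
Predictive draws are integers in $[0, n^*]$; their empirical
$\alpha/2, 1-\alpha/2$ quantiles give the interval, with both the
interpolating (type-7, default) and nearest-rank (type-1) rules exposed
since fractional limits on counts are a presentation choice.

## Exact distribution functions

[dbetabinom()], [pbetabinom()] and [qbetabinom()] evaluate the
beta-binomial pmf/cdf/quantile in log space (log-gamma throughout), which
stays exact to ~$10^{-12}$ at $n = 18{,}000$. They serve as the
"true quantile" oracle for the simulation engine and the test suite, and
back the `quantiles` CLI subcommand.

## The synthetic-data generator and what the tests can show

[rbetabinom_cluster()] / [rquasibinom_cluster()] / [simulate_hcd()] draw
clustered counts exactly from the models above; quasi-binomial sampling is
defined through the $\rho_h = (\phi-1)/(n_h-1)$ mapping per cluster, which
is exact in every balanced design (and all simulated settings are
balanced). Below $\rho = 10^{-12}$ plain binomial sampling avoids beta
shape overflow.

The generator emulates between-study heterogeneity of a single stratum
with known, fixed cluster sizes. It does not emulate features of real HCD
such as temporal drift, covariate shifts (supplier, personnel), unequal
or unknown cluster sizes, or within-study clustering below the group
level. Passing coverage tests therefore demonstrates correctness *under
the stated models*, not robustness to model misspecification.

## The simulation engine and problem sizes

[run_setting()] draws $S$ historical-set/future-count pairs, computes all
requested methods' limits, and reports two-sided and per-side coverages,
average limits and failure counts (a Bayesian non-convergence counts as a
failure, never silently). The data stream is generated before the methods
run and each method gets its own derived substream, so results for one
method are invariant to which others are requested. [mnt_grid()] (72
settings, $n = 18{,}000$) and [ltc_grid()] (96 settings, $n = 50$) expose
the two factorial designs; $n_h = n^*$ throughout.

The characterisation conditions are $S = 5000$, $B = 10{,}000$,
$C = 5000$ per setting — a cluster-scale computation over the full grids.
The package's own test suite runs a scaled-down profile chosen to keep
each check's Monte-Carlo error well inside its assertion band: $S = 500$,
$B = 2000$ for the 16-cell LTC coverage block (binomial SE
$\approx 0.01$ at $\psi = 0.95$ against an assertion band of
$[0.92, 0.98]$), $S = 2000$ for the equal-tail and np-chart checks, and
$S = 50$ replicates for the true-quantile tracking check, judged against
the per-run Monte-Carlo spread of the limits. The worked mortality
example is verified at the full $B = 10{,}000$ averaged over five seeds,
because the bisection tolerance band quantises single-run endpoints
(spacing $\approx 0.15$ events).

## Known limitations

* The average calibrated limits at rich histories ($H = 100$,
  $n = 18{,}000$, $\phi = 50$) sit a genuine but small ~0.5–0.8% outside
  the true 2.5%/97.5% quantiles — finite-$H$ conservatism that shrinks
  with history size but does not vanish at fixed $H$.
* The quasi-binomial model treats overdispersion as constant across
  cluster sizes; with unequal historical cluster sizes the beta-binomial
  model is the coherent choice, and the heuristics are not interpretable
  at all (the package warns).
* One future study only; simultaneous prediction for several future
  control groups is out of scope.
* Aggregated counts per control group only — no per-animal or per-well
  records, hence no within-study overdispersion modelling.
* The hierarchical Bayesian interval is included for completeness; its
  prior sensitivity and convergence fragility make it hard to recommend
  for routine use, and the coverage engine reports rather than repairs
  its failures.

## Worked example

Ten historical negative-control groups of 50 animals, mortality-like
(pooled proportion 0.276, slight overdispersion $\hat\phi = 1.31$):

```{r}
d <- simulate_hcd(H = 10, n = 50, pi = 0.276, phi = 1.31, seed = 7)
fit_quasibinomial(d)
prediction_interval(d, n_star = 50, model = "qb", B = 10000, seed = 1)
np_chart(d, n_star = 50)
```

The same computation driven from published summary estimates instead of
raw data uses the fit constructors directly:

```{r}
calibrate_interval(qb_fit(pi_hat = 0.276, phi_hat = 1.31),
                   n_h = rep(50, 10), n_star = 50, B = 10000, seed = 1)
```
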