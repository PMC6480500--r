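---
title: "Smoothing maternal and paternal age effects on rare birth outcomes"
author: "parage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smoothing maternal and paternal age effects on rare birth outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Children of older fathers tend also to be children of older mothers:
parental ages are strongly correlated, so the marginal association between
paternal age and a rare birth outcome such as Down syndrome is badly
confounded by maternal age.  Classical adjustments — treating the other
parent's age as linear, linear-plus-quadratic ("curvilinear"), or as 5-year
age bands — each leave something behind: polynomials fit well over one part
of the age range and poorly over another, and bands leave residual
confounding within a band.

`parage` takes the non-parametric route.  Age is kept to the nearest year
and each parent's full profile of age effects enters a binomial-logit model
under a first-order random-walk prior (equivalently, an intrinsic
conditional autoregressive prior on the line graph of ages), which smooths
each age's effect toward its one-year neighbours and nothing else.

## Model

Births are cross-tabulated by maternal age $j$ (15–49, $J = 35$) and
paternal age $k$ (15–65, $K = 51$).  With $n_{jk}$ births and $Y_{jk}$
cases per cell,

$$Y_{jk} \sim \mathrm{Binomial}(n_{jk}, \mu_{jk}), \qquad
\mathrm{logit}(\mu_{jk}) = \alpha + \mathrm{maternal}_j +
\mathrm{paternal}_k .$$

The joint model (`model3`) gives both parental vectors RW1 priors; the
marginal models (`model1`, `model2`) keep only one parent and collapse the
table over the other axis.  The RW1 log-density is, up to a constant,
$\tfrac{L-1}{2}\log\tau - \tfrac{\tau}{2}\sum_{a\ge 2}(\theta_a -
\theta_{a-1})^2$; it is improper in the overall level, so each CAR vector
is identified by a sum-to-zero constraint and the intercept carries the
level (the `car.normal` convention).  The intercept has a flat improper
prior in the CAR models; each CAR standard deviation $\sigma = 1/\sqrt\tau$
has a Uniform(0, 10) prior on the *open* interval — excluding the
boundaries keeps $\tau = \infty$ out of the sampler.  The comparison models
(`linear`, `curvilinear`, `category5`) use N(0, 1000) priors for the
intercept and all coefficients; the band scheme is 15–19 (reference),
20–24, …, 45–49, with paternal ages adding 50–54, 55–59 and 60–65.

Linear and quadratic age covariates are centred at the midpoint of each
parent's range (maternal 32, paternal 40).  This is a pure
reparameterisation chosen for sampler conditioning; fitted probabilities,
DIC and odds ratios are unchanged, and `linear_predictor()` documents the
parameterisation.

## Posterior computation

The default sampler is Pólya-Gamma data augmentation: given
$\omega_{jk} \sim \mathrm{PG}(n_{jk}, \psi_{jk})$ the full coefficient
vector is conditionally Gaussian with a sparse RW1-structured precision and
is drawn jointly.  The sum-to-zero constraints are imposed exactly by
conditioning-by-kriging: the ridge added along the constraint directions
does not change the distribution on the constraint subspace, so the
constrained draw is exact.  Each CAR precision has a truncated-Gamma full
conditional, sampled by inverse CDF on the truncated probability range —
the same distribution a rejection step would target, without an unbounded
loop.

PG(b, z) draws are exact (Devroye's alternating-series sampler) for cell
counts up to `pg_exact_max` (default 40 in `fit_parage()`) and use a
moment-matched Gaussian above it; the error of that approximation decays
like $1/\sqrt{b}$ and the single-cell oracle below checks the large-count
regime directly.

Pure PG augmentation mixes slowly when outcomes are rare (a few cases per
10,000 births): the augmented conditionals are much narrower than the
marginal posterior.  `fit_parage()` therefore interleaves
exact-likelihood Metropolis moves after every Gibbs draw: adaptive scalar
updates for the intercept and fixed effects, vectorised odd/even updates
over each CAR block (with neighbours held fixed the conditionals factorise
over ages), and a joint scale move that multiplies a CAR block and its
standard deviation by a common factor, which carries the chain through the
(sd, effects) funnel.  With these moves the standard protocol (5000
burn-in, 10,000 retained draws, 2 chains) reaches split-$\hat R$ below
1.05 on cohorts of 10 million births in a few minutes on one CPU.

Chains start "diverse": effects at zero, intercept at the empirical logit
of the overall rate plus chain-dependent offsets of $\pm 2$.  Everything is
driven by R's RNG, so a fit is bit-reproducible given its seed.  A
single-site adaptive random-walk sampler (`sampler = "rwm"`) targets the
same posterior and is used as a cross-check in the test suite.

## Model comparison and summaries

`dic()` reports the mean posterior deviance, the plug-in deviance at the
posterior mean of the cell probabilities $\mu_{jk}$ (the direct stochastic
parents of the counts — the classic BUGS focus), their difference pD
("complexity", the effective parameter count) and DIC = mean deviance +
pD.  On data with a nonlinear maternal risk curve the expected ordering is
CAR < curvilinear < 5-year bands < linear, with pD near 3 for the linear
model and near 5 for the curvilinear one.

`odds_ratios()` transforms draws, never summaries: per draw
$\mathrm{OR}_a = \exp(\theta_a - \theta_{\mathrm{ref}})$, then the 50th,
2.5th and 97.5th percentiles (equal-tailed, not HPD).  The default
baseline is the youngest age (15); `baseline = "overall_mean"` re-expresses
each draw relative to the weighted mean of the parent's age effects.  The
"overall mean risk" is not defined precisely anywhere authoritative; we
default to births-weighting, which makes the baseline the
population-average log-odds, and `weighted = FALSE` gives the unweighted
alternative.  Exceedance probabilities use the strict inequality OR > 1,
so ties — in particular the reference age itself — count as
non-exceedance.

## The synthetic cohort generator

Real cross-tabulations of this kind cannot be redistributed, so every test
runs on `simulate_crosstab()`.  Its defaults are fixed study conditions,
not tuning knobs: 10,293,589 births; a discretised bivariate-normal
age-pair law with maternal mean 29 (sd 6), paternal mean 32 (sd 7) and
correlation 0.8, chosen once as a qualitatively realistic description of a
national birth cohort's age structure; an overall prevalence of 5.4 per
10,000 (the intercept is solved by `uniroot` so the births-weighted mean
prevalence hits the target); a maternal log-odds ramp rising linearly
between ages 30 and 45 to an odds ratio of 18.9 versus age 15 (inflections
at 30 and 45, the shape reported for trisomies); and a flat paternal
truth.  Truth curves are returned centred to sum to zero so they are
directly comparable with the CAR estimates.

What the generator does *not* emulate: secular trends across cohort years,
age heaping and reporting error, missing paternal ages (all cells inside
the rectangle are observed), within-cell covariates, and the
selection effects of prenatal diagnosis and elective termination on birth
prevalence.  Passing recovery tests therefore show that the estimator
recovers a known additive log-odds surface under realistic confounding and
sparsity — not that any real-data estimate is unbiased with respect to
those unmodelled processes.

## Validation studies and problem sizes

The test suite and `run_validation()` use reduced problem sizes chosen to
exercise every code path while keeping a full run in the tens of minutes:

* single-cell oracle: an intercept-only model on one age (n = 2000, Y =
  40); under the flat logit prior the posterior of $\mu$ has density
  $\propto \mu^{Y-1}(1-\mu)^{n-Y-1}$, and the sampled draws are compared to
  a quadrature CDF by Kolmogorov–Smirnov distance (threshold 0.05,
  calibrated to the retained sample size);
* a 3-level CAR toy with fixed precision and Gaussian pseudo-likelihood,
  where the constrained draw's moments have a closed form;
* a recovery study: 50 replicates of a scaled-down ramp/null scenario
  (300,000 births, prevalence 2 per 1000, maternal ramp to OR 8, flat
  paternal truth, correlation 0.8) fitted with 500 burn-in + 1000 draws;
  pooled 95%-interval coverage of the centred truth must lie in (0.85, 1];
* the confounding demonstration: on a 2-million-birth cohort with a flat
  paternal truth, the marginal paternal OR at 45 rises above 1.5 while the
  adjusted curve stays flat with its interval covering 1;
* seed determinism of the simulate-fit-summarise pipeline.

## Numerical choices and edge cases

* Cells with zero births stay in the table and contribute exactly zero
  likelihood; the grid stays rectangular.
* Cholesky factorisation of the (ridged) conditional precision retries
  once with a small jitter if the matrix is numerically semidefinite.
* For a CAR block of length 2 the truncated-Gamma shape degenerates; the
  precision is then drawn by grid inverse-CDF on the log-sd scale.
* An all-zero-case table triggers a warning (the intercept is then only
  weakly identified by the prior's tail behaviour).
* `read_crosstab()` refuses to repair data: missing cells inside the
  declared rectangle, duplicated cells, fractional or negative counts and
  cases exceeding births all name the offending cell.  BUGS-style
  `structure(.Data = ..., .Dim = c(J, K))` blocks are read in row-major
  order, the S-PLUS/BUGS convention.

## Known limitations

DIC is the only fit criterion (no WAIC/LOO); the model is additive on the
log-odds scale with no maternal-by-paternal interaction; RW2 or spline
priors are not offered; and absolute-risk (prevalence-scale) predictions
per age pair are out of scope.  The age-15 baseline inherits the sparsity
of the youngest ages: its posterior is wide, and odds ratios against it
are correspondingly variable from cohort to cohort even when the adjusted
curves themselves are stable.
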