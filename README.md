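# parage

Bayesian smoothing of maternal and paternal age effects on rare binary
birth outcomes.

## The problem

Parental ages are strongly correlated — older fathers usually have older
partners — so the apparent effect of paternal age on a rare outcome such
as Down syndrome is confounded by maternal age, and the usual adjustments
(linear, linear + quadratic, or 5-year age bands for the other parent)
leave residual bias wherever the true log-odds curve is nonlinear.
`parage` is for epidemiologists and biostatisticians who want to
disentangle the two ages without imposing a parametric shape.

## The model

Births are cross-tabulated by maternal age *j* (15–49) and paternal age
*k* (15–65).  With *n<sub>jk</sub>* births and *Y<sub>jk</sub>* cases,

```
Y_jk ~ Binomial(n_jk, mu_jk)
logit(mu_jk) = alpha + maternal_j + paternal_k
```

Each parental profile receives a first-order random-walk (intrinsic CAR)
prior — each age's effect is smoothed toward its one-year neighbours, with
the smoothing standard deviation given a Uniform(0, 10) prior — identified
by a sum-to-zero constraint, with a flat prior on the intercept.  Fitting
is by a Pólya-Gamma Gibbs sampler with interleaved exact-likelihood
Metropolis moves (rare outcomes make pure augmentation sticky).  Marginal
single-parent models and the classic linear / curvilinear / 5-year-band
alternatives are fitted by the same machinery and compared by DIC.
Posterior draws become age-specific odds ratios (vs age 15, or vs the
overall mean risk) with equal-tailed 95% credible intervals and
exceedance probabilities.  A synthetic-cohort generator with correlated
parental ages and known truth curves backs the validation suite.

## A worked example

```r
library(parage)
scn <- sim_scenario(total_births = 1e6)     # DS-like synthetic cohort
sim <- simulate_crosstab(scn, seed = 42)
sim$tab
#> Age cross-tabulation [synthetic]: 35 maternal ages (15-49) x 51 paternal ages (15-65)
#>   births: 1,000,000   cases: 584   crude prevalence: 5.84 per 10,000

fit <- fit_parage(sim$tab, "model3", burn_in = 1000, samples = 3000, seed = 42)
fit
#> Bayesian parental-age model [synthetic]: maternal = car, paternal = car
#>   sampler: pg, 2 chain(s) x 3000 draws (burn-in 1000, thin 1), seed 42
#>   DIC 1470.2 (mean deviance 1450.6, pD 19.7)
#>   max split-R-hat 1.038 (converged)

ort <- odds_ratios(fit, "maternal")
ort[ort$age %in% c(15, 30, 40, 45), ]
#>  age median lower upper exceedance
#>   15   1.00 1.000  1.00      0.000
#>   30   2.08 0.877  5.92      0.951
#>   40  11.83 4.699 34.54      1.000
#>   45  24.50 9.615 77.91      1.000
```

The maternal odds ratio is flat through the twenties, rises steeply on the
log scale after age 30 and reaches roughly 25-fold (credible interval
10–78) at age 45 relative to age 15 — the generating truth for this cohort
was a ramp to 18.9, well inside the interval at this cohort size.  The
exceedance column is the posterior probability that the OR exceeds 1.
`plot(fit)` draws both parents' OR curves with ribbons;
`odds_ratios(fit, "paternal")` shows the adjusted paternal curve staying
near 1 even though the *marginal* paternal curve (`fit_parage(sim$tab,
"model2", ...)`) rises spuriously through the age correlation.

`run_analysis()` scripts the whole comparison (six model presets, OR
tables, convergence reports, a DIC comparison table in the classic
layout, and comparison figures); `inst/cli/parage.R` exposes
`simulate` / `fit` / `summarize` / `validate` / `reproduce` subcommands
for shell use.

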