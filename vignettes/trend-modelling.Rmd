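---
title: "Hierarchical trend modelling of winter count-circle surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical trend modelling of winter count-circle surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(grebetrends)
```

## The problem

Winter count-circle surveys (the Christmas Bird Count being the canonical
example) record, once per winter, every bird detected within a fixed
24.1-km-diameter circle, along with the observer hours expended and the
mode of transport.  They are the only data source with the spatial and
temporal reach to detect continental-scale changes in wintering waterbird
distributions, but they are noisy in characteristic ways: effort varies
enormously between circles and years, some surveys are skipped, counts
are over-dispersed relative to Poisson, and for *Aechmophorus* grebes a
fraction of birds is reported only at genus level because western and
Clark's grebes are hard to separate at distance.

`grebetrends` implements the full analysis chain for such data: screening
and species-resolving the survey table, a hierarchical Bayesian count
model with a nonlinear effort correction, posterior predictive checking,
effort-standardized abundance indices with missing-survey imputation,
geometric-mean trend estimation, and the abundance-weighted latitudinal
centre of occurrence whose displacement measures a range shift.

## The count model

Each analysed count $C_{i,t}$ (circle $i$, year $t$, species categories
pooled after allocation) is modelled as

$$C_{i,t} \sim \mathrm{Poisson}(\mu_{i,t}),$$
$$\log \mu_{i,t} = \beta_{0,r(i)} + \beta_{1,r(i)}\,(t - \bar t)
  + \beta_2\, \mathrm{boat}_{i,t} + \gamma_i + \delta_t
  + f(\zeta_{i,t}) + \varepsilon_{i,t},$$

with region intercepts $\beta_{0,r}$ and log-linear trends
$\beta_{1,r}$, a binary boat-use effect $\beta_2$ (specific boat hours
are not recorded, so a binary covariate is the honest resolution),
circle effects $\gamma_i \sim N(0, \sigma^2_{\mathrm{circle}})$, year
effects beyond trend $\delta_t \sim N(0, \sigma^2_{\mathrm{year}})$
shared across regions, and an observation-level noise term
$\varepsilon_{i,t} \sim N(0, \sigma^2_{\mathrm{noise}})$ that makes the
counts over-dispersed.  Time is centred at the series midpoint, which
decorrelates intercepts from trends.  Year effects are taken as global
rather than region-specific — the more parsimonious reading where the
model description leaves the choice open.

The effort sub-model is

$$f(\zeta) = B\,\frac{(\zeta/\zeta_m)^p - 1}{p},$$

where $\zeta$ is total survey hours, $\zeta_m$ the mean over all counts,
and $(B, p)$ shape the effort-detection relationship: $p = 1$ is linear
in relative effort, $p < 1$ saturating, and $p \to 0$ logarithmic.  A
single global $(B, p)$ pair is fitted for all regions.  Because effort
enters only through $\zeta/\zeta_m$, rescaling all effort values leaves
the model invariant — a property the test suite checks.  `effort_effect()`
is continuous in $p$: below $p = 10^{-4}$ it switches to the
second-order series $B(\ell + p\ell^2/2)$, $\ell = \log(\zeta/\zeta_m)$,
so tiny positive $p$ never hits 0/0.  $p$ itself is kept positive by
sampling $\log p$ with a diffuse normal prior (mean 0, variance 10).

Region coefficients are drawn from common distributions,
$\beta_{0,r} \sim N(\mu_{\beta_0}, \sigma^2_{\mathrm{region}})$ and
$\beta_{1,r} \sim N(\mu_{\beta_1}, \sigma^2_{\mathrm{trend}})$.  With a
single region this hierarchy is undefined, so single-region fits place
the vague coefficient prior on $\beta_0$ and $\beta_1$ directly.

### Priors

All fixed coefficients and hyper-means take $N(0, 10^3)$ priors.  All
variance components take inverse-gamma(0.001, 0.001) priors
(equivalently gamma priors on the precisions), including the variance
of the effort coefficient $B$.  These are the conventional vague
choices for this model family; the inverse-gamma is known to be
influential when a variance component is near zero, which is why
`hyperpriors()` exposes rather than hard-wires it.

### Identifiability and parameterization

Circle effects within a region and an overall intercept are confounded,
as are year effects and trend.  The package resolves this with
sum-to-zero constraints: in `log_posterior()` — the package's reference
statement of the model density — circle effects must sum to zero within
each region and year effects across years, and violating parameters get
$-\infty$ rather than an exception, so any sampler can simply reject
them.

The JAGS program used by `fit()` expresses the same posterior in
hierarchically centred form: the latent log count $\eta_{i,t}$ is
normal around the regression mean, and circle intercepts
$a_i \sim N(\beta_{0,r(i)}, \sigma^2_{\mathrm{circle}})$ absorb the
region intercept (the circle *deviation* is $a_i - \beta_{0,r}$).
Centring makes the linear coefficients conditionally conjugate, which
JAGS's `glm` samplers exploit; in the flat parameterization the same
chains mix orders of magnitude more slowly because the several hundred
observation-level noise terms are updated one at a time against a
nearly rigid likelihood.  Year effects remain explicitly centred
(`yeff = yeff_raw - mean(yeff_raw)`).  The test suite pins the JAGS
program to `log_posterior()` indirectly, through parameter recovery and
through an independent direct-summation oracle for the density itself.

### Sampling protocol

`mcmc_config()` defaults to two chains and a burn-in of 10,000
iterations — the production protocol.  Every chain's RNG is seeded
deterministically from the configuration seed, so identical calls
return identical draws.  Convergence is assessed per monitored
parameter by split-$\hat R$ (computed by `split_rhat()`, checked in the
tests against an independently coded textbook formula) and by the
ratio of the Monte Carlo standard error to the posterior sd
(via effective sample size); a fit is flagged converged when every
structural parameter has $\hat R \le 1.1$ and MC error/sd $\le 0.05$.
The per-observation latent log counts are excluded from the verdict:
they are auxiliary, numerous, and individually weakly informed.

## Posterior predictive checking

At every retained draw the package generates a replicate dataset from
the fitted $\mu_{i,t}$ (including the noise term, so the replicate
carries the same over-dispersion) and compares the observed and
replicated discrepancies.  "Sums of squared error" is implemented, by
default, as squared Pearson residuals $\sum (C - \mu)^2/\mu$ — the
standard variance-scaled choice for Poisson checks — with the raw sum
of squares available via `type = "squared"` since the scaling
convention is a genuinely open choice.  The Bayesian p-value is the
fraction of draws whose replicated discrepancy is at least the observed
one; ties count toward the numerator (they matter only in degenerate
integer cases).  Values near 0.5 indicate a well-fitting model.  On
data simulated from the model itself the p-value concentrates well
inside (0.2, 0.8), which is the desk-scale surrogate for the check on
real data (a real-data p-value is data-dependent and cannot be
reproduced without the original observations).

## Derived quantities

**Abundance index.**  For each region and year, every circle's predicted
count is exponentiated at *standardized* covariates — mean effort
($f = 0$), no boat, noise at its zero mean — and averaged over all the
region's circles, including circles whose survey is missing that year;
those are thereby imputed through the posterior rather than dropped.
Standardizing is a design choice: the model statement only requires
controlling for effort, but holding all sampling covariates fixed is
what makes indices comparable across circles and years.  Intervals are
central (equal-tailed) 2.5%/97.5% posterior quantiles throughout.

**Trend.**  The annual percent change is the geometric mean of
proportional changes between the first and last modeled years,
$100\,[(I_T/I_1)^{1/(T-1)} - 1]$, computed per posterior draw; a trend
is significant when the 95% interval excludes zero.  A log-linear
regression through all years is available (`method = "regression"`) but
the endpoint form is the default, matching the stated estimator.  Two
exact identities tie the estimators together and are tested: when the
index is purely log-linear the geometric-mean trend equals
$100(e^{\beta_1} - 1)$, and compounding the geometric-mean trend over
$T-1$ intervals recovers the total change $100(I_T/I_1 - 1)$ for any
positive series.

**Centre of occurrence.**  The abundance-weighted mean latitude
$\sum m_i y_i / \sum m_i$ over all circles, computed per draw from the
model-corrected counts; the difference between two years, times
111.195 km per degree of latitude (meridian arc on a mean-radius
sphere), is the range shift in kilometres.  The constant is documented
because no standard conversion reproduces every published km figure
exactly from rounded centre latitudes; the package reports both the
degree shift and its km conversion.

## The synthetic-data generator

Because no public accession accompanies the original survey extracts,
the package ships a generator (`simulate_dataset()`) whose generative
model is *exactly* the analysis model, plus the survey artefacts around
it: independent Bernoulli missingness per circle-year, log-normal
effort hours, Bernoulli boat use, a per-region CLARK fraction, and
binomial thinning of each count into genus-level records.  A truth
sidecar records every realized parameter and per-record expectation, so
recovery can be measured.

The default scenario (`default_config()`) is calibrated to the
published survey-wide figures: four regions whose mean counts (934,
661, 63, 11) span the observed two orders of magnitude, generating
trends of −9.29, +4.30, +6.70 and +0.60 %/yr, circle sd 1.87 (the
published among-circle figure), boat effect 0.031, and a genus-level
reporting rate of 13.9%.  Values the source does not report were chosen
once at realistic magnitudes and not revisited: year-effect sd 0.1,
noise sd 0.3, effort log-normal(log 50, 0.5) hours, boat probability
0.2, missing probability 0.1.  Independent missingness cannot
reproduce the strongly heterogeneous published coverage bins (30.7% of
circles complete alongside 19% missing 11–18 years implies per-circle
missingness rates, not a shared one); 0.1 is a middle ground and the
knob is configurable.  Single-region validation scenarios
(`single_region_config()`) use circle sd 1.0 so that a 13–30 circle
region spans a realistic but not extreme abundance range.

What the generator does *not* emulate — observer-skill heterogeneity,
spatial autocorrelation between circles, weather — bounds what passing
tests show: they demonstrate that the estimation machinery recovers the
truth under the model's own assumptions plus the survey artefacts
above, not that the model is robust to violations it never sees.

## Numerical choices

* Counts are rounded half-to-even before entering the Poisson
  likelihood; species allocation is fractional (conserving each
  circle-year total exactly) and rounding happens at the last step.
* Missing surveys are encoded by record absence, never by zero, and
  contribute nothing to the likelihood.
* Log means are clamped to $\pm 700$ before exponentiation in
  replication, so degenerate draws replicate as zeros instead of NaN.
* Records with unknown effort hours are rejected at read time — the
  effort model has no honest value to give them.
* Coast distance is an input column; the 50-km coastal/interior rule is
  applied to the supplied value (a circle at exactly 50 km is
  interior).  Computing distances from coastline geometry is out of
  scope.
* The region rule table is ordered configuration data, not code; the
  eight-region default is replaceable wholesale.
* Unidentified-count allocation falls back deterministically when a
  count identified no birds: region-year pooled ratio, then region
  all-years ratio, then an explicit warning with the count left
  unallocated.
* Manifests are written with 17 significant digits so every double
  round-trips exactly and a manifest re-run reproduces outputs bit for
  bit.

## Validation problem sizes

The package's own validation uses deliberately compact designs: the
single-region recovery experiments use 13–30 circles over 36 years with
2,000 retained draws per chain after a 2,000-iteration burn-in
(convergence diagnostics vouch for each fit individually; adaptation
plus burn-in several times the mixing time of the centred sampler), and
the interval-calibration and posterior-predictive batteries use 20
replicates of six circles over 16 years.  These sizes make the full
suite a desk-scale computation while leaving the recovery tolerances —
the published 95% interval half-widths — comfortably dominated by
estimation rather than Monte Carlo error.

## Known limitations

* The trend estimand of the endpoint geometric mean includes the
  realized year-effect difference between the first and last years (of
  order $\sigma_{\mathrm{year}}\sqrt{2}/(T-1)$ per year, ~0.4 %/yr at
  the defaults); with strong trends this is negligible, for
  near-stable regions the regression form is steadier.
* The inverse-gamma(0.001, 0.001) prior can distort variance components
  that are truly near zero; refit with an alternative prior via
  `hyperpriors()` when a component's posterior piles up at its lower
  boundary.
* With a single region the between-region variance shares reported for
  multi-region fits have no analogue, and `sigma_region`/`sigma_trend`
  are not monitored.
* The boat covariate is additive on the log scale; any interaction
  between boat use and hours is unidentifiable from a binary flag.
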