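# grebetrends

Hierarchical Bayesian trend and range-shift analysis for winter
count-circle surveys (Christmas Bird Count style data), built for the
question it was designed around: how the wintering population of
*Aechmophorus* grebes changed across western North America, region by
region, over 36 annual surveys.

Counts are modelled as hierarchical over-dispersed Poisson variables,

    C[i,t] ~ Poisson(mu[i,t])
    log mu[i,t] = beta0[r(i)] + beta1[r(i)] * (t - tbar) + beta2 * boat[i,t]
                  + gamma[i] + delta[t] + f(zeta[i,t]) + eps[i,t]

with region-specific intercepts and log-linear trends drawn from common
distributions, circle effects `gamma`, year effects beyond trend
`delta`, observation-level noise `eps` (the over-dispersion), a binary
boat-use covariate, and the nonlinear effort correction
`f(zeta) = B * ((zeta/zeta_m)^p - 1) / p` in total survey hours.
Coefficients take N(0, 10^3) priors and variances inverse-gamma(0.001,
0.001); fitting is two-chain MCMC through JAGS with split-R-hat and
MC-error/sd convergence checks.  On top of the fit the package computes
posterior predictive checks with a Bayesian p-value, effort-standardized
regional abundance indices that impute missing surveys, geometric-mean
annual trends with 95% credible intervals, and the abundance-weighted
latitudinal centre of occurrence whose between-year displacement
measures a range shift in km.

Because the original survey extracts are not redistributable, the
package includes a calibrated synthetic-data generator
(`simulate_dataset()`) whose generative model is exactly the analysis
model, with a ground-truth sidecar; every downstream stage is validated
by parameter recovery against it.

## Worked example

The `analysis/` directory holds the staged workflow (simulate, prepare,
fit, check, derive); each script consumes and emits files under
`results/analysis/`.  The condensed equivalent:

```r
library(grebetrends)

sim <- simulate_dataset(default_config(seed = 20260925))  # 4 regions, 1975-2010
d   <- allocate_unidentified(filter_circles(assign_region(sim$dataset, overwrite = TRUE)))
f   <- fit(d, mcmc_config(burn_in = 10000, n_samples = 8000, seed = 20260925))

geometric_mean_trend(f)
bayesian_p_value(f)
range_shift(f, 1980, 2010)
```

which prints (generating trends were −9.29, +4.30, +6.70, +0.60 %/yr):

```
                    region percent lower95 upper95 significant cumulative_pct
         Northern Interior   0.717 -0.0899    1.54       FALSE           28.4
                Salish Sea  -9.031 -9.5334   -8.52        TRUE          -96.4
 Southern California Coast   4.536  3.9251    5.14        TRUE          372.5
     Southwestern Interior   6.757  6.0960    7.43        TRUE          886.1
               continental  -3.439 -3.9362   -2.95        TRUE          -70.6

Bayesian p-value: 0.535
Centre of occurrence: 46.75 deg N (1980) -> 36.37 deg N (2010),
a southward shift of 1154 km
```

Each row is a region's posterior mean annual percent change with its
95% credible interval; `significant` flags intervals excluding zero,
and `cumulative_pct` compounds the annual rate over the 35 year
intervals (the steeply declining region loses 96% of its index while
the southern regions more than quadruple — which is what drags the
abundance-weighted centre of the distribution south).  A Bayesian
p-value near 0.5 says the fitted model reproduces its own data's
dispersion.

The methods vignette (`vignettes/trend-modelling.Rmd`) documents the
model, priors, identifiability constraints, sampler parameterization,
and the design decisions behind every derived quantity.

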