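# independent reference implementations used to pin the package's
# numerics; written directly from the model definition, sharing no code
# with the package internals

oracle_dinvgamma <- function(x, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}

# direct summation of the log posterior for a single-region dataset laid
# out as parallel vectors
oracle_log_posterior_1region <- function(counts, years, circle_ids, effort,
                                         boat, year_span, params, priors) {
  zeta_m <- mean(effort)
  t_mid <- mean(range(year_span))
  all_years <- year_span[1]:year_span[2]
  lp <- 0
  for (k in seq_along(counts)) {
    f <- params$effort_B *
      ((effort[k] / zeta_m)^params$effort_p - 1) / params$effort_p
    lmu <- params$beta0 + params$beta1 * (years[k] - t_mid) +
      params$beta2 * boat[k] +
      params$circle_effects[[circle_ids[k]]] +
      params$year_effects[[as.character(years[k])]] +
      f + params$noise[k]
    lp <- lp + counts[k] * lmu - exp(lmu) - lgamma(counts[k] + 1)
  }
  for (ce in params$circle_effects)
    lp <- lp + dnorm(ce, 0, sqrt(params$var_circle), log = TRUE)
  for (ye in params$year_effects)
    lp <- lp + dnorm(ye, 0, sqrt(params$var_year), log = TRUE)
  for (nn in params$noise)
    lp <- lp + dnorm(nn, 0, sqrt(params$var_noise), log = TRUE)
  sdc <- sqrt(priors$coef_var)
  lp + dnorm(params$beta0, priors$coef_mean, sdc, log = TRUE) +
    dnorm(params$beta1, priors$coef_mean, sdc, log = TRUE) +
    dnorm(params$beta2, priors$coef_mean, sdc, log = TRUE) +
    dnorm(params$effort_B, 0, sqrt(params$var_B), log = TRUE) +
    oracle_dinvgamma(params$var_B, priors$prec_shape, priors$prec_scale) +
    dnorm(log(params$effort_p), priors$logp_mean, sqrt(priors$logp_var), log = TRUE) +
    oracle_dinvgamma(params$var_circle, priors$prec_shape, priors$prec_scale) +
    oracle_dinvgamma(params$var_year, priors$prec_shape, priors$prec_scale) +
    oracle_dinvgamma(params$var_noise, priors$prec_shape, priors$prec_scale)
}

# textbook split-R-hat: halve each chain, then classical Gelman-Rubin
# over the halves
oracle_split_rhat <- function(chain_list) {
  halves <- list()
  for (ch in chain_list) {
    n2 <- floor(length(ch) / 2)
    halves <- c(halves, list(ch[1:n2]), list(ch[(length(ch) - n2 + 1):length(ch)]))
  }
  n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  W <- mean(vapply(halves, var, 0))
  B <- n / (length(halves) - 1) * sum((means - mean(means))^2)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# random single-region parameter set satisfying the model constraints
random_params_1region <- function(circle_ids, all_years, n_obs) {
  ce <- rnorm(length(circle_ids)); ce <- ce - mean(ce)
  ye <- rnorm(length(all_years), 0, 0.3); ye <- ye - mean(ye)
  list(beta0 = rnorm(1, 3, 1), beta1 = rnorm(1, 0, 0.05),
       beta2 = rnorm(1, 0, 0.1),
       effort_B = rnorm(1, 0.5, 0.2), effort_p = runif(1, 0.5, 2),
       circle_effects = setNames(ce, circle_ids),
       year_effects = setNames(ye, as.character(all_years)),
       noise = rnorm(n_obs, 0, 0.3),
       var_circle = runif(1, 0.5, 2), var_year = runif(1, 0.05, 0.5),
       var_noise = runif(1, 0.05, 0.5), var_B = runif(1, 0.5, 2))
}
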