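#' Hyperprior settings
#'
#' The fixed-effect coefficients (region intercept and trend
#' hyper-means, boat effect) take normal priors with mean 0 and variance
#' 10^3; all variance components take inverse-gamma priors with shape
#' and scale 0.001 (equivalently gamma priors on the precisions).  The
#' effort coefficient B takes a normal prior whose variance itself has
#' the inverse-gamma hyperprior, and the effort shape p is constrained
#' positive through a diffuse normal prior on log(p).  The inverse-gamma
#' 0.001/0.001 choice is conventional but known to be influential for
#' variance components that are near zero; it is therefore exposed here
#' rather than hard-wired.
#'
#' @param coef_mean,coef_var normal prior for coefficients (0, 10^3)
#' @param prec_shape,prec_scale inverse-gamma prior for variances
#' @param logp_mean,logp_var normal prior for log(p)
#' @return object of class `hyperpriors`
#' @export
hyperpriors <- function(coef_mean = 0, coef_var = 1000,
                        prec_shape = 0.001, prec_scale = 0.001,
                        logp_mean = 0, logp_var = 10) {
  stopifnot(coef_var > 0, prec_shape > 0, prec_scale > 0, logp_var > 0)
  structure(list(coef_mean = coef_mean, coef_var = coef_var,
                 prec_shape = prec_shape, prec_scale = prec_scale,
                 logp_mean = logp_mean, logp_var = logp_var),
            class = "hyperpriors")
}

#' MCMC sampler settings
#'
#' Defaults follow the analysis protocol for production fits: two
#' chains and a burn-in of 10,000 iterations before samples are drawn.
#' Validation studies at known truth typically use shorter chains,
#' which the convergence diagnostics then vouch for.
#'
#' @param n_chains number of chains (>= 2; R-hat needs at least two)
#' @param burn_in iterations discarded after adaptation
#' @param n_samples posterior draws kept per chain
#' @param thinning thinning interval
#' @param n_adapt JAGS adaptation iterations
#' @param seed integer seed; chain RNGs are derived deterministically
#' @return object of class `mcmc_config`
#' @export
mcmc_config <- function(n_chains = 2, burn_in = 10000, n_samples = 2000,
                        thinning = 1, n_adapt = 500, seed = 1L) {
  stopifnot(n_chains >= 2, burn_in >= 0, n_samples >= 10, thinning >= 1,
            n_adapt >= 100)
  structure(list(n_chains = as.integer(n_chains), burn_in = as.integer(burn_in),
                 n_samples = as.integer(n_samples), thinning = as.integer(thinning),
                 n_adapt = as.integer(n_adapt), seed = as.integer(seed)),
            class = "mcmc_config")
}

# Collapse species rows to one analysed total per surveyed circle-year and
# attach the model indexing (region/circle/year indices, centred time,
# relative effort).  Counts are rounded half-to-even so the Poisson
# likelihood always sees integers even after fractional species allocation.
aggregate_counts <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  rec <- dataset$records
  if (nrow(rec) == 0) stop("dataset has no records")
  circles <- dataset$circles
  if (all(is.na(circles$region))) circles$region <- "all"
  if (anyNA(circles$region))
    stop("some circles lack a region assignment; run assign_region() first")

  key <- paste(rec$circle_id, rec$year, sep = "\r")
  first <- !duplicated(key)
  obs <- data.frame(circle_id = rec$circle_id[first], year = rec$year[first],
                    effort_hours = rec$effort_hours[first],
                    boat_used = rec$boat_used[first], stringsAsFactors = FALSE)
  tot <- tapply(rec$count, key, sum)
  obs$count <- round(as.numeric(tot[key[first]]))

  region_names <- sort(unique(circles$region))
  circles$creg <- match(circles$region, region_names)
  circles <- circles[order(circles$creg, circles$circle_id), , drop = FALSE]
  circles$cidx <- seq_len(nrow(circles))
  rownames(circles) <- NULL

  years <- dataset$year_range[1]:dataset$year_range[2]
  t_mid <- mean(range(years))
  zeta_m <- mean(obs$effort_hours)

  obs$cidx <- circles$cidx[match(obs$circle_id, circles$circle_id)]
  obs$region_idx <- circles$creg[obs$cidx]
  obs$yidx <- match(obs$year, years)
  obs$tc <- obs$year - t_mid
  obs$ez <- obs$effort_hours / zeta_m
  obs <- obs[order(obs$cidx, obs$year), , drop = FALSE]
  rownames(obs) <- NULL

  cstart <- vapply(seq_along(region_names), function(r) min(circles$cidx[circles$creg == r]), 0)
  cend <- vapply(seq_along(region_names), function(r) max(circles$cidx[circles$creg == r]), 0)

  list(obs = obs, circles = circles, region_names = region_names,
       years = years, t_mid = t_mid, zeta_m = zeta_m,
       cstart = as.integer(cstart), cend = as.integer(cend))
}

#' Linear predictor of the count model
#'
#' Assembles the log expected count for one survey record:
#' region intercept + region trend x centred year + boat effect +
#' circle effect + year effect + effort adjustment + noise.
#'
#' @param record list or one-row data frame with `year`, `effort_hours`,
#'   `boat_used`
#' @param circle list or one-row data frame with `circle_id` and `region`
#' @param params named list carrying `beta0` and `beta1` (named by
#'   region), `beta2`, `effort_B`, `effort_p`, `circle_effects` (named by
#'   circle), `year_effects` (named by year), `zeta_m`, `t_mid`, and
#'   optionally `noise` (a single value for this record; default 0)
#' @return the log-scale expected count
#' @export
log_expected_count <- function(record, circle, params) {
  region <- as.character(circle$region)
  cid <- as.character(circle$circle_id)
  if (!region %in% names(params$beta0) || !region %in% names(params$beta1))
    stop("lookup error: region '", region, "' not indexed in params")
  if (!cid %in% names(params$circle_effects))
    stop("lookup error: circle '", cid, "' not indexed in params")
  yr <- as.character(record$year)
  if (!yr %in% names(params$year_effects))
    stop("lookup error: year ", yr, " not indexed in params")
  noise <- if (is.null(params$noise)) 0 else params$noise
  unname(params$beta0[[region]] +
           params$beta1[[region]] * (record$year - params$t_mid) +
           params$beta2 * record$boat_used +
           params$circle_effects[[cid]] +
           params$year_effects[[yr]] +
           effort_effect(record$effort_hours, params$effort_B, params$effort_p,
                         params$zeta_m) +
           noise)
}

dinvgamma_log <- function(x, shape, scale) {
  if (x <= 0) return(-Inf)
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}

#' Unnormalized log posterior density
#'
#' Sum of the Poisson log likelihood over the observed (surveyed)
#' circle-years and the log densities of every random effect and
#' hyperprior.  Missing surveys contribute nothing.  Parameter values
#' that violate the model's constraints (non-positive variances or
#' effort shape, random effects that do not satisfy the sum-to-zero
#' identifiability constraints) return `-Inf` rather than raising, so a
#' sampler can simply reject them.
#'
#' This density is the package's reference statement of the model; the
#' JAGS program used by [fit()] is checked against it in the test suite.
#'
#' @param params named list as in [log_expected_count()], plus `noise`
#'   (vector, one element per observed circle-year in the order of the
#'   aggregated dataset), variances `var_circle`, `var_year`,
#'   `var_noise`, `var_B`, and for multi-region data the hyper
#'   parameters `mu_beta0`, `mu_beta1`, `var_beta0`, `var_beta1`
#' @param dataset a [survey_dataset] with regions assigned
#' @param priors a [hyperpriors] object
#' @param tol tolerance for the sum-to-zero constraints
#' @return the unnormalized log posterior (a finite number, or `-Inf`
#'   for constraint-violating parameters)
#' @export
log_posterior <- function(params, dataset, priors = hyperpriors(), tol = 1e-6) {
  agg <- aggregate_counts(dataset)
  R <- length(agg$region_names)

  vars <- c(params$var_circle, params$var_year, params$var_noise, params$var_B)
  if (R > 1) vars <- c(vars, params$var_beta0, params$var_beta1)
  if (any(!is.finite(vars)) || any(vars <= 0)) return(-Inf)
  if (!is.finite(params$effort_p) || params$effort_p <= 0) return(-Inf)

  ce <- params$circle_effects
  for (r in agg$region_names) {
    ids <- agg$circles$circle_id[agg$circles$region == r]
    if (abs(sum(ce[ids])) > tol * max(1, length(ids))) return(-Inf)
  }
  ye <- params$year_effects
  if (abs(sum(ye)) > tol * max(1, length(ye))) return(-Inf)

  obs <- agg$obs
  noise <- params$noise
  if (length(noise) != nrow(obs))
    stop("params$noise must hold one value per observed circle-year (",
         nrow(obs), ")")
  b0 <- params$beta0[agg$region_names[obs$region_idx]]
  b1 <- params$beta1[agg$region_names[obs$region_idx]]
  lmu <- b0 + b1 * obs$tc + params$beta2 * obs$boat_used +
    ce[obs$circle_id] + ye[as.character(obs$year)] +
    effort_effect(obs$effort_hours, params$effort_B, params$effort_p, agg$zeta_m) +
    noise
  lp <- sum(dpois(obs$count, exp(lmu), log = TRUE))

  lp <- lp + sum(dnorm(ce, 0, sqrt(params$var_circle), log = TRUE))
  lp <- lp + sum(dnorm(ye, 0, sqrt(params$var_year), log = TRUE))
  lp <- lp + sum(dnorm(noise, 0, sqrt(params$var_noise), log = TRUE))

  coef_sd <- sqrt(priors$coef_var)
  if (R > 1) {
    lp <- lp + sum(dnorm(params$beta0, params$mu_beta0, sqrt(params$var_beta0), log = TRUE))
    lp <- lp + sum(dnorm(params$beta1, params$mu_beta1, sqrt(params$var_beta1), log = TRUE))
    lp <- lp + dnorm(params$mu_beta0, priors$coef_mean, coef_sd, log = TRUE)
    lp <- lp + dnorm(params$mu_beta1, priors$coef_mean, coef_sd, log = TRUE)
    lp <- lp + dinvgamma_log(params$var_beta0, priors$prec_shape, priors$prec_scale)
    lp <- lp + dinvgamma_log(params$var_beta1, priors$prec_shape, priors$prec_scale)
  } else {
    lp <- lp + dnorm(params$beta0, priors$coef_mean, coef_sd, log = TRUE)
    lp <- lp + dnorm(params$beta1, priors$coef_mean, coef_sd, log = TRUE)
  }
  lp <- lp + dnorm(params$beta2, priors$coef_mean, coef_sd, log = TRUE)
  lp <- lp + dnorm(params$effort_B, 0, sqrt(params$var_B), log = TRUE)
  lp <- lp + dinvgamma_log(params$var_B, priors$prec_shape, priors$prec_scale)
  lp <- lp + dnorm(log(params$effort_p), priors$logp_mean, sqrt(priors$logp_var), log = TRUE)
  lp <- lp + dinvgamma_log(params$var_circle, priors$prec_shape, priors$prec_scale)
  lp <- lp + dinvgamma_log(params$var_year, priors$prec_shape, priors$prec_scale)
  lp <- lp + dinvgamma_log(params$var_noise, priors$prec_shape, priors$prec_scale)
  unname(lp)
}

# JAGS program.  The model is written in the hierarchically centred
# parameterization: the latent log count eta is centred on the regression
# mean and the circle intercepts a[j] are centred on their region
# intercept.  This is a pure reparameterization of the same posterior
# (circle deviations are a[j] - beta0[region]) but it makes the linear
# coefficients conditionally conjugate, which the glm module exploits;
# the flat parameterization mixes orders of magnitude more slowly.
jags_model_string <- function(R, priors) {
  coef_prec <- format(1 / priors$coef_var, scientific = TRUE)
  g <- sprintf("dgamma(%g, %g)", priors$prec_shape, priors$prec_scale)
  region_block <- if (R > 1) sprintf("
  for (r in 1:R) {
    beta0[r] ~ dnorm(mu_beta0, tau_beta0)
    beta1[r] ~ dnorm(mu_beta1, tau_beta1)
  }
  mu_beta0 ~ dnorm(%g, %s)
  mu_beta1 ~ dnorm(%g, %s)
  tau_beta0 ~ %s
  tau_beta1 ~ %s
  sigma_region <- 1 / sqrt(tau_beta0)
  sigma_trend <- 1 / sqrt(tau_beta1)",
    priors$coef_mean, coef_prec, priors$coef_mean, coef_prec, g, g)
  else sprintf("
  beta0[1] ~ dnorm(%g, %s)
  beta1[1] ~ dnorm(%g, %s)",
    priors$coef_mean, coef_prec, priors$coef_mean, coef_prec)

  sprintf("model {
  for (k in 1:N) {
    C[k] ~ dpois(exp(eta[k]))
    eta[k] ~ dnorm(m[k], tau_noise)
    m[k] <- a[cidx[k]] + beta1[reg[k]] * tc[k] + beta2 * boat[k] +
      yeff[yidx[k]] + B * (pow(ez[k], p) - 1) / p
  }
  for (j in 1:J) { a[j] ~ dnorm(beta0[creg[j]], tau_circ) }
  for (t in 1:T) { yeff_raw[t] ~ dnorm(0, tau_year) }
  for (t in 1:T) { yeff[t] <- yeff_raw[t] - mean(yeff_raw) }
%s
  beta2 ~ dnorm(%g, %s)
  tau_B ~ %s
  B ~ dnorm(0, tau_B)
  log_p ~ dnorm(%g, %g)
  p <- exp(log_p)
  tau_circ ~ %s
  tau_year ~ %s
  tau_noise ~ %s
  sigma_circle <- 1 / sqrt(tau_circ)
  sigma_year <- 1 / sqrt(tau_year)
  sigma_noise <- 1 / sqrt(tau_noise)
}", region_block, priors$coef_mean, coef_prec, g,
    priors$logp_mean, 1 / priors$logp_var, g, g, g)
}

#' Fit the hierarchical trend model by MCMC
#'
#' Fits the over-dispersed Poisson model with region-specific intercepts
#' and trends, circle and year random effects, the boat covariate and
#' the nonlinear effort sub-model, using JAGS with the `glm` samplers.
#' With two or more regions the region coefficients are drawn from a
#' common normal distribution with vague hyperpriors; a single-region
#' dataset takes the vague priors directly (the hierarchy is undefined
#' there).  Chains are seeded deterministically from the configuration
#' seed, so identical calls return identical draws.
#'
#' @param dataset a filtered [survey_dataset] with regions assigned
#' @param mcmc an [mcmc_config]
#' @param priors a [hyperpriors]
#' @param monitor_noise keep the per-observation latent log counts
#'   (`eta`)?  Required for posterior predictive checks; adds one
#'   monitored node per observation.
#' @param quiet suppress JAGS progress output
#' @return object of class `cbc_fit`: the `coda::mcmc.list` of draws,
#'   the model indexing, the convergence table and a `converged` flag
#'   (R-hat <= 1.1 and MC error/sd <= 0.05 for every monitored
#'   structural parameter).
#' @export
fit <- function(dataset, mcmc = mcmc_config(), priors = hyperpriors(),
                monitor_noise = TRUE, quiet = TRUE) {
  stopifnot(inherits(mcmc, "mcmc_config"), inherits(priors, "hyperpriors"))
  agg <- aggregate_counts(dataset)
  obs <- agg$obs
  if (length(unique(obs$circle_id)) < 2 || length(unique(obs$year)) < 2)
    stop("unidentifiable model: need at least two circles and two years")
  R <- length(agg$region_names)

  data <- list(N = nrow(obs), C = obs$count, tc = obs$tc, boat = obs$boat_used,
               cidx = obs$cidx, yidx = obs$yidx, ez = obs$ez,
               J = nrow(agg$circles), T = length(agg$years),
               creg = agg$circles$creg, reg = obs$region_idx)
  if (R > 1) data$R <- R

  lc <- log(obs$count + 0.5)
  a0 <- tapply(lc, obs$cidx, mean)
  a_init <- rep(mean(lc), data$J)
  a_init[as.integer(names(a0))] <- a0
  inits <- lapply(seq_len(mcmc$n_chains), function(i) {
    ii <- list(.RNG.name = "base::Wichmann-Hill",
               .RNG.seed = (mcmc$seed * 97 + i) %% 2147483629,
               beta0 = rep(mean(lc), R), beta1 = rep(0, R), beta2 = 0,
               B = 0, log_p = 0, eta = lc, a = as.numeric(a_init),
               yeff_raw = rep(0, data$T),
               tau_circ = 1, tau_year = 1, tau_noise = 1, tau_B = 1)
    if (R > 1) { ii$mu_beta0 <- mean(lc); ii$mu_beta1 <- 0
                 ii$tau_beta0 <- 1; ii$tau_beta1 <- 1 }
    ii
  })

  monitors <- c("beta0", "beta1", "beta2", "B", "p",
                "sigma_circle", "sigma_year", "sigma_noise", "a", "yeff")
  if (R > 1) monitors <- c(monitors, "mu_beta0", "mu_beta1",
                           "sigma_region", "sigma_trend")
  if (monitor_noise) monitors <- c(monitors, "eta")

  model_string <- jags_model_string(R, priors)
  rjags::load.module("glm", quiet = TRUE)
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = mcmc$n_chains,
                          n.adapt = mcmc$n_adapt, quiet = quiet)
  if (mcmc$burn_in > 0) {
    if (quiet) invisible(utils::capture.output(
      update(jm, mcmc$burn_in, progress.bar = "none")))
    else update(jm, mcmc$burn_in)
  }
  samples <- rjags::coda.samples(jm, variable.names = monitors,
                                 n.iter = mcmc$n_samples * mcmc$thinning,
                                 thin = mcmc$thinning,
                                 progress.bar = if (quiet) "none" else "text")

  out <- structure(list(samples = samples, agg = agg, mcmc = mcmc,
                        priors = priors, model_string = model_string,
                        n_regions = R), class = "cbc_fit")
  out$diagnostics <- convergence_diagnostics(out)
  out$converged <- isTRUE(attr(out$diagnostics, "converged"))
  out
}

#' @export
print.cbc_fit <- function(x, ...) {
  cat("<cbc_fit>  hierarchical over-dispersed Poisson trend model\n")
  cat("  regions:", x$n_regions, "  circles:", nrow(x$agg$circles),
      "  observations:", nrow(x$agg$obs), "\n")
  cat("  chains:", x$mcmc$n_chains, " draws/chain:", x$mcmc$n_samples,
      " burn-in:", x$mcmc$burn_in, "\n")
  cat("  converged:", x$converged, "\n")
  b1 <- fit_param_matrix(x, "beta1")
  pct <- 100 * (exp(colMeans(b1)) - 1)
  for (r in seq_along(x$agg$region_names))
    cat(sprintf("  %-32s %+.2f %%/yr\n", x$agg$region_names[r], pct[r]))
  invisible(x)
}

# stack chains into one draws matrix without relying on coda's
# (unregistered in some sessions) as.matrix method
samples_matrix <- function(samples) {
  do.call(rbind, lapply(samples, function(ch) {
    m <- unclass(ch)
    attr(m, "mcpar") <- NULL
    m
  }))
}

# draws for one parameter family as a matrix (iterations x elements),
# robust to JAGS dropping the [1] suffix on length-one vectors
fit_param_matrix <- function(fit, name) {
  m <- samples_matrix(fit$samples)
  cols <- grep(paste0("^", name, "(\\[|$)"), colnames(m))
  if (length(cols) == 0) stop("parameter '", name, "' was not monitored")
  idx <- sub(paste0("^", name, "\\[?([0-9]*)\\]?$"), "\\1", colnames(m)[cols])
  ord <- order(as.integer(ifelse(idx == "", "1", idx)))
  m[, cols[ord], drop = FALSE]
}
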