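#' Discrepancy between observed and expected counts
#'
#' Sum of squared errors between counts and their model means.  The
#' default variance-scales each term by the Poisson mean (squared
#' Pearson residuals, `sum((obs - mu)^2 / mu)`); `type = "squared"`
#' gives the raw sum of squares.
#'
#' @param observed vector of counts
#' @param expected vector of model means, same length, all > 0
#' @param type `"pearson"` (default) or `"squared"`
#' @return a non-negative number
#' @export
discrepancy <- function(observed, expected, type = c("pearson", "squared")) {
  type <- match.arg(type)
  if (length(observed) != length(expected))
    stop("alignment error: observed and expected differ in length")
  if (any(!is.finite(expected)) || any(expected <= 0))
    stop("expected counts must be positive")
  if (type == "pearson") sum((observed - expected)^2 / expected)
  else sum((observed - expected)^2)
}

#' Replicate a dataset at one posterior draw
#'
#' Draws one Poisson replicate per observed circle-year at that draw's
#' expected count.  Missing surveys remain missing.  The log mean is
#' clamped to [-700, 700] so degenerate draws replicate as zeros (or
#' fail loudly at overflow) instead of propagating NaN.
#'
#' @param params_draw either a full parameter list as accepted by
#'   [log_expected_count()] (with `noise` a per-observation vector), or
#'   a list with element `log_mu` giving the per-observation log means
#'   directly
#' @param dataset a [survey_dataset] with regions assigned
#' @param seed optional seed for the replicate draw (global RNG state is
#'   restored on exit when given)
#' @return data frame with `circle_id`, `year`, `mu` and the replicated
#'   `count_rep`, in aggregated observation order
#' @export
replicate_dataset <- function(params_draw, dataset, seed = NULL) {
  agg <- aggregate_counts(dataset)
  obs <- agg$obs
  if (!is.null(params_draw$log_mu)) {
    lmu <- params_draw$log_mu
    if (length(lmu) != nrow(obs))
      stop("alignment error: log_mu must have one element per observation")
  } else {
    noise <- params_draw$noise
    if (is.null(noise)) noise <- rep(0, nrow(obs))
    lmu <- vapply(seq_len(nrow(obs)), function(k) {
      pk <- params_draw; pk$noise <- noise[k]
      log_expected_count(obs[k, ],
                         agg$circles[agg$circles$circle_id == obs$circle_id[k], ],
                         pk)
    }, numeric(1))
  }
  lmu <- pmin(pmax(lmu, -700), 700)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  data.frame(circle_id = obs$circle_id, year = obs$year, mu = exp(lmu),
             count_rep = rpois(nrow(obs), exp(lmu)), stringsAsFactors = FALSE)
}

#' Posterior predictive check
#'
#' For every posterior draw, compares the observed data's discrepancy
#' with that of a replicate dataset generated at the same draw, and
#' reports the Bayesian p-value: the fraction of draws whose replicated
#' discrepancy is at least the observed one (ties count).  Values near
#' 0.5 indicate a well-fitting model; values near 0 or 1 indicate
#' misfit.  In the paired scatter, a good fit puts about half the
#' points above the 1:1 line.
#'
#' @param fit a `cbc_fit` fitted with `monitor_noise = TRUE`
#' @param type discrepancy scaling, see [discrepancy()]
#' @param seed seed for the replicate draws (default derives from the
#'   fit's own seed, so the check is reproducible)
#' @return object of class `ppc_result`: list with `bayesian_p` and the
#'   per-draw `pairs` (`draw`, `d_obs`, `d_rep`)
#' @export
posterior_predictive_check <- function(fit, type = c("pearson", "squared"),
                                       seed = NULL) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "cbc_fit"))
  eta <- fit_param_matrix(fit, "eta")
  obs <- fit$agg$obs
  if (ncol(eta) != nrow(obs))
    stop("fit does not carry per-observation noise; refit with monitor_noise = TRUE")
  if (is.null(seed)) seed <- fit$mcmc$seed + 7L

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  mu <- exp(pmin(pmax(eta, -700), 700))
  nd <- nrow(mu)
  d_obs <- numeric(nd); d_rep <- numeric(nd)
  C <- obs$count
  for (d in seq_len(nd)) {
    mud <- mu[d, ]
    rep_d <- rpois(length(mud), mud)
    d_obs[d] <- discrepancy(C, mud, type)
    d_rep[d] <- discrepancy(rep_d, mud, type)
  }
  structure(list(bayesian_p = mean(d_rep >= d_obs),
                 pairs = data.frame(draw = seq_len(nd), d_obs = d_obs,
                                    d_rep = d_rep),
                 type = type), class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat("<ppc_result>  posterior predictive check (", x$type, " discrepancy)\n",
      sep = "")
  cat("  draws:", nrow(x$pairs), "  Bayesian p-value:",
      format(x$bayesian_p, digits = 3), "\n")
  cat("  (values near 0.5 indicate a well-fitting model)\n")
  invisible(x)
}

#' Bayesian p-value of a fitted model
#'
#' Convenience wrapper around [posterior_predictive_check()] returning
#' just the p-value, with the discrepancy pairs attached as an
#' attribute.
#'
#' @inheritParams posterior_predictive_check
#' @return the Bayesian p-value in [0, 1]
#' @export
bayesian_p_value <- function(fit, type = c("pearson", "squared"), seed = NULL) {
  ppc <- posterior_predictive_check(fit, type, seed)
  structure(ppc$bayesian_p, pairs = ppc$pairs)
}
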