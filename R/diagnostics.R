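#' Split potential scale reduction factor
#'
#' The split form of the Gelman-Rubin statistic: each chain is halved,
#' the halves are treated as chains, and
#' `R-hat = sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean
#' within-chain variance and `B` the between-chain variance of the
#' means.  Splitting makes within-chain drift visible even when the
#' chains agree marginally.
#'
#' @param x matrix of draws, iterations in rows and chains in columns
#' @return the split R-hat (1 for constant chains)
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n2 <- floor(nrow(x) / 2)
  if (n2 < 2) stop("need at least 4 iterations per chain")
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j)
    cbind(x[seq_len(n2), j], x[nrow(x) - n2 + seq_len(n2), j])))
  n <- nrow(halves)
  W <- mean(apply(halves, 2, var))
  B <- n * var(colMeans(halves))
  if (!is.finite(W) || W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence diagnostics for a fitted model
#'
#' Per monitored parameter: posterior mean and sd, split R-hat, the
#' effective sample size, and the ratio of the Monte Carlo standard
#' error to the posterior sd.  The fit is regarded as converged when
#' every structural parameter has R-hat at most `rhat_max` and MC
#' error/sd at most `mcse_max`; the per-observation noise terms are
#' excluded from the verdict (they are auxiliary and number in the
#' hundreds).
#'
#' @param x a `cbc_fit` or a `coda::mcmc.list` with >= 2 chains
#' @param rhat_max R-hat threshold (default 1.1)
#' @param mcse_max MC error/sd threshold (default 0.05)
#' @param exclude regex of parameter names left out of the verdict
#' @return data frame of diagnostics with a logical `converged`
#'   attribute
#' @export
convergence_diagnostics <- function(x, rhat_max = 1.1, mcse_max = 0.05,
                                    exclude = "^eta") {
  samples <- if (inherits(x, "cbc_fit")) x$samples else x
  if (!inherits(samples, "mcmc.list"))
    samples <- coda::as.mcmc.list(samples)
  if (length(samples) < 2)
    stop("diagnostic error: R-hat is undefined for a single chain")
  mats <- lapply(samples, function(ch) {
    m <- unclass(ch)
    attr(m, "mcpar") <- NULL
    m
  })
  pars <- colnames(mats[[1]])
  ess <- coda::effectiveSize(samples)
  out <- data.frame(parameter = pars, mean = NA_real_, sd = NA_real_,
                    rhat = NA_real_, ess = NA_real_, mcse_sd = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(pars)) {
    xp <- vapply(mats, function(m) m[, i], numeric(nrow(mats[[1]])))
    out$mean[i] <- mean(xp)
    out$sd[i] <- sd(as.vector(xp))
    out$rhat[i] <- split_rhat(xp)
    out$ess[i] <- unname(ess[pars[i]])
    out$mcse_sd[i] <- if (out$sd[i] == 0) 0 else 1 / sqrt(max(out$ess[i], 1e-12))
  }
  core <- !grepl(exclude, out$parameter)
  attr(out, "converged") <- all(out$rhat[core] <= rhat_max, na.rm = TRUE) &&
    all(out$mcse_sd[core] <= mcse_max, na.rm = TRUE)
  attr(out, "thresholds") <- c(rhat_max = rhat_max, mcse_max = mcse_max)
  out
}
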