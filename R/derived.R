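KM_PER_DEGREE_LAT <- 111.195

# per-draw regional index matrices (draws x years), at standardized
# covariates: mean effort, no boat, observation noise at its zero mean.
# The index for a region-year is the mean over ALL its circles of the
# exponentiated predicted log count, so missing surveys are imputed
# through the posterior rather than dropped.
index_draws <- function(fit, include_continental = TRUE) {
  a <- fit_param_matrix(fit, "a")
  b1 <- fit_param_matrix(fit, "beta1")
  ye <- fit_param_matrix(fit, "yeff")
  agg <- fit$agg
  tc <- agg$years - agg$t_mid
  ea <- exp(a)
  out <- list()
  for (r in seq_along(agg$region_names)) {
    jj <- agg$circles$cidx[agg$circles$creg == r]
    mean_ea <- rowMeans(ea[, jj, drop = FALSE])
    out[[agg$region_names[r]]] <- mean_ea * exp(outer(b1[, r], tc) + ye)
  }
  if (include_continental && length(agg$region_names) >= 1) {
    J <- nrow(agg$circles)
    tot <- 0
    for (r in seq_along(agg$region_names)) {
      jj <- agg$circles$cidx[agg$circles$creg == r]
      tot <- tot + rowSums(ea[, jj, drop = FALSE]) * exp(outer(b1[, r], tc))
    }
    out[["continental"]] <- tot / J * exp(ye)
  }
  out
}

#' Effort-standardized abundance index
#'
#' The predicted mean count per circle in each region and year,
#' standardized to mean survey effort with no boat and the
#' observation-level noise at its zero mean, averaged over every circle
#' in the region (so circles with missing surveys are imputed from the
#' posterior), and summarized across draws as the posterior mean with a
#' central 95% credible interval.
#'
#' @param fit a `cbc_fit`
#' @param regions regions to report (default all, plus `"continental"`)
#' @param years years to report (default the full modeled span)
#' @return data frame `region`, `year`, `index`, `lower95`, `upper95`,
#'   with the per-draw index matrices attached as `attr(, "draws")`
#' @export
abundance_index <- function(fit, regions = NULL, years = NULL) {
  stopifnot(inherits(fit, "cbc_fit"))
  draws <- index_draws(fit)
  if (is.null(regions)) regions <- names(draws)
  bad <- setdiff(regions, names(draws))
  if (length(bad) > 0)
    stop("extrapolation error: region(s) outside the fitted model: ",
         paste(bad, collapse = ", "))
  all_years <- fit$agg$years
  if (is.null(years)) years <- all_years
  if (!all(years %in% all_years))
    stop("extrapolation error: year(s) outside the fitted range: ",
         paste(setdiff(years, all_years), collapse = ", "))
  yi <- match(years, all_years)
  out <- do.call(rbind, lapply(regions, function(r) {
    m <- draws[[r]][, yi, drop = FALSE]
    data.frame(region = r, year = years, index = colMeans(m),
               lower95 = apply(m, 2, quantile, 0.025),
               upper95 = apply(m, 2, quantile, 0.975),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "draws") <- draws[regions]
  out
}

#' Geometric-mean annual trend
#'
#' The annualized percent change computed as the geometric mean of
#' proportional changes between the first and last values of an index
#' series: `100 * ((I_T / I_1)^(1/(T-1)) - 1)`.  For a fitted model the
#' statistic is computed per posterior draw of the regional abundance
#' index, yielding a posterior mean with a 95% credible interval and a
#' significance flag (interval excludes zero).  `method = "regression"`
#' instead uses the slope of a per-draw log-linear regression through
#' all years.
#'
#' @param x a positive numeric index series, or a `cbc_fit`
#' @param ... passed to methods
#' @return for a numeric series, the annual percent change; for a fit,
#'   a data frame `region`, `percent`, `lower95`, `upper95`,
#'   `significant`
#' @export
geometric_mean_trend <- function(x, ...) UseMethod("geometric_mean_trend")

#' @rdname geometric_mean_trend
#' @export
geometric_mean_trend.numeric <- function(x, ...) {
  if (length(x) < 2) stop("need at least two time points")
  if (any(!is.finite(x)) || any(x <= 0))
    stop("domain error: index series must be positive")
  100 * ((x[length(x)] / x[1])^(1 / (length(x) - 1)) - 1)
}

#' @rdname geometric_mean_trend
#' @param regions regions to report (default all plus continental)
#' @param method `"endpoints"` (the geometric-mean estimator, default)
#'   or `"regression"` (log-linear slope through all years)
#' @export
geometric_mean_trend.cbc_fit <- function(x, regions = NULL,
                                         method = c("endpoints", "regression"),
                                         ...) {
  method <- match.arg(method)
  draws <- index_draws(x)
  if (is.null(regions)) regions <- names(draws)
  yrs <- x$agg$years
  Tn <- length(yrs)
  out <- do.call(rbind, lapply(regions, function(r) {
    m <- draws[[r]]
    g <- if (method == "endpoints") {
      100 * ((m[, Tn] / m[, 1])^(1 / (Tn - 1)) - 1)
    } else {
      lm_slopes <- (log(m) %*% (yrs - mean(yrs))) / sum((yrs - mean(yrs))^2)
      100 * (exp(as.vector(lm_slopes)) - 1)
    }
    lo <- unname(quantile(g, 0.025)); hi <- unname(quantile(g, 0.975))
    data.frame(region = r, percent = mean(g), lower95 = lo, upper95 = hi,
               significant = lo > 0 | hi < 0, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cumulative percent change from an annual rate
#'
#' Compounds an annual percent change over a number of year intervals:
#' `100 * ((1 + annual/100)^n - 1)`.  An annual decline of 2.07% over
#' the 35 intervals of a 36-year series compounds to about a 52%
#' decline.
#'
#' @param annual_percent annual percent change (> -100)
#' @param n_intervals number of year-to-year intervals
#' @return total percent change over the period
#' @export
cumulative_change <- function(annual_percent, n_intervals) {
  if (any(annual_percent <= -100))
    stop("annual_percent must be greater than -100")
  100 * ((1 + annual_percent / 100)^n_intervals - 1)
}

#' Abundance-weighted centre of occurrence
#'
#' The latitude of the centre of mass of a set of survey circles with
#' counts as mass: `sum(m_i * y_i) / sum(m_i)`.
#'
#' @param counts non-negative weights (model-corrected counts), at least
#'   one positive
#' @param latitudes circle latitudes, same length
#' @return the centre-of-mass latitude in degrees
#' @export
centre_of_latitude <- function(counts, latitudes) {
  if (length(counts) != length(latitudes))
    stop("alignment error: counts and latitudes differ in length")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be non-negative")
  if (sum(counts) == 0)
    stop("undefined centre: all counts are zero")
  weighted.mean(latitudes, counts)
}

#' Convert a latitudinal shift to kilometres
#'
#' Absolute difference in degrees latitude times 111.195 km per degree
#' (the meridian arc length on a mean-radius sphere).
#'
#' @param centre_a,centre_b latitudes in degrees
#' @param km_per_degree conversion constant (default 111.195)
#' @return distance in km
#' @export
latitudinal_shift_km <- function(centre_a, centre_b,
                                 km_per_degree = KM_PER_DEGREE_LAT) {
  abs(centre_a - centre_b) * km_per_degree
}

#' Posterior centre of occurrence by year
#'
#' For each posterior draw, computes every circle's model-corrected
#' count at standardized effort and the resulting abundance-weighted
#' mean latitude; summarizes across draws.
#'
#' @param fit a `cbc_fit`
#' @param years years to evaluate (default the full modeled span)
#' @return data frame `year`, `latitude`, `lower95`, `upper95`, with
#'   per-draw centres attached as `attr(, "draws")`
#' @export
range_centre <- function(fit, years = NULL) {
  stopifnot(inherits(fit, "cbc_fit"))
  agg <- fit$agg
  if (is.null(years)) years <- agg$years
  if (!all(years %in% agg$years))
    stop("extrapolation error: year(s) outside the fitted range")
  a <- fit_param_matrix(fit, "a")
  b1 <- fit_param_matrix(fit, "beta1")
  ye <- fit_param_matrix(fit, "yeff")
  lat <- agg$circles$latitude
  creg <- agg$circles$creg
  centres <- matrix(NA_real_, nrow(a), length(years))
  for (yi in seq_along(years)) {
    tc <- years[yi] - agg$t_mid
    ti <- match(years[yi], agg$years)
    lmu <- a + b1[, creg, drop = FALSE] * tc + ye[, ti]
    w <- exp(lmu)
    centres[, yi] <- (w %*% lat) / rowSums(w)
  }
  out <- data.frame(year = years, latitude = colMeans(centres),
                    lower95 = apply(centres, 2, quantile, 0.025),
                    upper95 = apply(centres, 2, quantile, 0.975))
  rownames(out) <- NULL
  attr(out, "draws") <- centres
  out
}

#' Latitudinal shift of the centre of occurrence between two years
#'
#' Per posterior draw, the difference in the abundance-weighted centre
#' latitude between two years, summarized with a 95% credible interval
#' and converted to kilometres.  Negative shifts are southward.
#'
#' @param fit a `cbc_fit`
#' @param year_a,year_b the two years to compare
#' @param km_per_degree conversion constant (default 111.195)
#' @return one-row data frame with the two centre latitudes, the shift
#'   in degrees (posterior mean and 95% CI) and its magnitude in km
#' @export
range_shift <- function(fit, year_a, year_b,
                        km_per_degree = KM_PER_DEGREE_LAT) {
  rc <- range_centre(fit, years = c(year_a, year_b))
  d <- attr(rc, "draws")
  delta <- d[, 2] - d[, 1]
  data.frame(year_a = year_a, year_b = year_b,
             latitude_a = rc$latitude[1], latitude_b = rc$latitude[2],
             shift_degrees = mean(delta),
             lower95 = unname(quantile(delta, 0.025)),
             upper95 = unname(quantile(delta, 0.975)),
             shift_km = abs(mean(delta)) * km_per_degree)
}
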