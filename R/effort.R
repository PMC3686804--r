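#' Nonlinear effort adjustment
#'
#' Log-scale effect of survey effort on the expected count,
#' `f(zeta) = B * ((zeta/zeta_m)^p - 1) / p`, where `zeta_m` is the mean
#' effort over all counts.  The family spans a wide range of
#' effort-detection relationships: `p = 1` is linear in relative effort,
#' `p < 1` saturating, and the `p -> 0` limit is `B * log(zeta/zeta_m)`.
#' The function is continuous in `p`: below `p_threshold` the
#' second-order series expansion around `p = 0` is used, so tiny
#' positive `p` never hits a 0/0.
#'
#' @param zeta survey effort hours (vectorized, must be > 0)
#' @param B effort coefficient
#' @param p shape parameter, must be > 0
#' @param zeta_m mean effort hours (> 0)
#' @param p_threshold switch-over to the series expansion (default 1e-4)
#' @return the log-scale effort adjustment, zero at `zeta = zeta_m`.
#' @export
#' @examples
#' effort_effect(60, B = 1, p = 1, zeta_m = 60)   # 0 at mean effort
#' effort_effect(120, B = 1, p = 1, zeta_m = 60)  # 1
effort_effect <- function(zeta, B, p, zeta_m, p_threshold = 1e-4) {
  if (any(!is.finite(zeta)) || any(zeta <= 0))
    stop("domain error: effort hours must be positive")
  if (!is.finite(zeta_m) || zeta_m <= 0)
    stop("domain error: zeta_m must be positive")
  if (!is.finite(p) || p <= 0)
    stop("domain error: p must be positive")
  l <- log(zeta / zeta_m)
  if (p < p_threshold) {
    # f = B*(exp(p*l)-1)/p = B*(l + p*l^2/2 + O(p^2))
    B * (l + p * l^2 / 2)
  } else {
    B * (exp(p * l) - 1) / p
  }
}
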