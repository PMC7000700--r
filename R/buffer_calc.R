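#' Free calcium in a 1:1 Ca-EGTA buffer
#'
#' Solves the single-ligand binding equilibrium
#' \eqn{Ca + EGTA \rightleftharpoons CaEGTA} with apparent dissociation
#' constant `kd_app` for the free calcium concentration: the unique
#' non-negative root of
#' \eqn{x^2 + (K_d + EGTA_{tot} - Ca_{tot})x - K_d\,Ca_{tot} = 0}.
#' All three inputs must share one concentration unit; the result is in
#' that unit. The default `kd_app` of 0.4315 uM (431.5 nM, with
#' concentrations in uM) is the apparent Ca-EGTA constant calibrated so
#' that 65 uM total calcium in 1 mM EGTA gives 30 nM free calcium (pH 7.0,
#' 150 mM KCl assay conditions); chelator calculators applying full
#' pH/ionic-strength corrections can imply somewhat different apparent
#' constants, so `kd_app` is a parameter.
#'
#' @param total_ca Total calcium (>= 0). Vectorized.
#' @param total_egta Total EGTA (>= 0).
#' @param kd_app Apparent Ca-EGTA dissociation constant (> 0).
#' @return Free calcium concentration, same unit as the inputs.
#' @examples
#' free_ca(65, 1000, 0.4315)  # ~0.030 uM = 30 nM
#' @export
free_ca <- function(total_ca, total_egta, kd_app = 0.4315) {
  if (any(total_ca < 0) || any(total_egta < 0))
    stop("concentrations must be non-negative")
  if (any(kd_app <= 0)) stop("`kd_app` must be positive")
  b <- kd_app + total_egta - total_ca
  # numerically stable quadratic root (avoids cancellation for b > 0)
  disc <- sqrt(b^2 + 4 * kd_app * total_ca)
  free <- ifelse(b >= 0, 2 * kd_app * total_ca / (b + disc), (disc - b) / 2)
  pmin(free, total_ca)  # guard rounding at the free = total boundary
}

#' Total calcium needed for a target free calcium
#'
#' Closed-form inverse of [free_ca()]: the bound calcium at free
#' concentration x is \eqn{EGTA_{tot}\, x / (K_d + x)}, so
#' \eqn{Ca_{tot} = x + EGTA_{tot}\, x/(K_d + x)}. Round-trips with
#' [free_ca()] to high precision.
#'
#' @param target_free Desired free calcium (>= 0). Vectorized.
#' @param total_egta Total EGTA (>= 0).
#' @param kd_app Apparent dissociation constant (> 0).
#' @return Total calcium in the inputs' unit.
#' @examples
#' total_ca_for_free(0.030, 1000, 0.4315)  # ~65 uM
#' @export
total_ca_for_free <- function(target_free, total_egta, kd_app = 0.4315) {
  if (any(target_free < 0)) stop("`target_free` must be non-negative")
  if (any(total_egta < 0)) stop("`total_egta` must be non-negative")
  if (any(kd_app <= 0)) stop("`kd_app` must be positive")
  target_free + total_egta * target_free / (kd_app + target_free)
}
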