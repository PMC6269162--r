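## Forward two-state van't Hoff model shared by the simulator and fitters.
## Temperatures are handled in kelvin internally; every interface is in C.

.toK <- function(tC) tC + 273.15

#' Fraction of unfolded protein under a van't Hoff model
#'
#' For each transition the unfolding equilibrium constant is
#' \deqn{K(T) = \exp\left[\frac{|\Delta H|}{R}\left(\frac{1}{T_m} -
#'   \frac{1}{T}\right)\right]}
#' with temperatures in kelvin and \eqn{|\Delta H|} in J/mol, so that
#' \eqn{K(T_m) = 1} and the per-transition unfolded fraction
#' \eqn{f_i = K/(1+K)} equals 1/2 at \eqn{T_m}. The overall fraction is the
#' amplitude-weighted sum over the model's transitions.
#'
#' @param model an [UnfoldingModel()].
#' @param temperatureC strictly increasing temperature grid, degrees C.
#' @return numeric vector of unfolded fractions in \[0, 1\], non-decreasing
#'   along the grid.
#' @examples
#' m <- UnfoldingModel(tm = 34.1, dh = -455.8)
#' fractionUnfolded(m, 34.1)  # 0.5 by construction
#' @export
fractionUnfolded <- function(model, temperatureC) {
  stopifnot(is(model, "UnfoldingModel"))
  validObject(model)
  if (any(!is.finite(temperatureC)))
    stop("temperature grid must be finite", call. = FALSE)
  if (length(temperatureC) > 1L && any(diff(temperatureC) <= 0))
    stop("temperature grid must be strictly increasing", call. = FALSE)
  tr <- model@transitions
  TK <- .toK(temperatureC)
  f <- numeric(length(TK))
  for (i in seq_len(nrow(tr))) {
    lnK <- (abs(tr$dh[i]) * 1000 / .RGAS) * (1 / .toK(tr$tm[i]) - 1 / TK)
    f <- f + tr$amplitude[i] * stats::plogis(lnK)   # K/(1+K)
  }
  f
}

#' Raw CD signal predicted from an unfolding model
#'
#' Mixes the linear folded and unfolded baselines by the unfolded fraction:
#' \code{signal(T) = baselineFolded(T) * (1 - f) + baselineUnfolded(T) * f}.
#'
#' @inheritParams fractionUnfolded
#' @return numeric vector of raw signal values on the grid.
#' @export
signalFromFraction <- function(model, temperatureC) {
  f <- fractionUnfolded(model, temperatureC)
  bf <- model@baselineFolded[1] + model@baselineFolded[2] * temperatureC
  bu <- model@baselineUnfolded[1] + model@baselineUnfolded[2] * temperatureC
  bf * (1 - f) + bu * f
}

#' Slope of the unfolded fraction at the midpoint
#'
#' For a single two-state transition the analytic identity
#' \eqn{df/dT|_{T_m} = |\Delta H| / (4 R T_m^2)} links the steepness of the
#' melt at its midpoint to the van't Hoff enthalpy; this is also how peak
#' heights of the derivative curve convert to enthalpies.
#'
#' @param tm melting temperature, degrees C.
#' @param dh van't Hoff enthalpy, kJ/mol (sign ignored).
#' @return slope in fraction per degree C.
#' @export
vantHoffSlopeAtTm <- function(tm, dh) {
  abs(dh) * 1000 / (4 * .RGAS * .toK(tm)^2)
}

## inverse of the above: enthalpy (kJ/mol, magnitude) from a per-component
## derivative peak height normalized by its amplitude
.dhFromPeak <- function(tm, heightOverAmplitude) {
  4 * .RGAS * .toK(tm)^2 * heightOverAmplitude / 1000
}
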