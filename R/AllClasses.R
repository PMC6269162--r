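#' @import methods
#' @importFrom stats coef fitted lm median nls.control optimise quantile resid
#'   rnorm sd setNames vcov
#' @importFrom utils head read.table tail write.csv
NULL

## Gas constant, J mol^-1 K^-1
.RGAS <- 8.314

.HEPTAD <- c("a", "b", "c", "d", "e", "f", "g")

#' Build a transition table for an unfolding model
#'
#' A transition is one two-state unfolding event of the coiled coil,
#' described by its melting temperature \code{tm} (degrees C), its apparent
#' van't Hoff enthalpy \code{dh} (kJ/mol, reported negative by the field's
#' sign convention for these CD melts) and the fraction \code{amplitude} of
#' the total unfolding signal it carries.
#'
#' @param tm numeric vector of melting temperatures, degrees C (0-100).
#' @param dh numeric vector of van't Hoff enthalpies, kJ/mol; the sign is
#'   ignored internally (the magnitude sets the steepness) and results are
#'   reported negative.
#' @param amplitude numeric vector of signal fractions in (0, 1]; must sum
#'   to 1 across the table.
#' @return a data.frame with columns \code{tm}, \code{dh}, \code{amplitude},
#'   sorted by ascending \code{tm}.
#' @examples
#' transitionTable(tm = c(29.2, 43.2), dh = c(-256.8, -466.2),
#'                 amplitude = c(0.6, 0.4))
#' @export
transitionTable <- function(tm, dh, amplitude = rep(1 / length(tm), length(tm))) {
  tr <- data.frame(tm = as.numeric(tm), dh = as.numeric(dh),
                   amplitude = as.numeric(amplitude))
  tr <- tr[order(tr$tm), , drop = FALSE]
  rownames(tr) <- NULL
  msg <- .validTransitions(tr)
  if (!isTRUE(msg)) stop(msg, call. = FALSE)
  tr
}

.validTransitions <- function(tr) {
  if (!is.data.frame(tr) || !all(c("tm", "dh", "amplitude") %in% names(tr)))
    return("transitions must be a data.frame with columns tm, dh, amplitude")
  if (nrow(tr) < 1L || nrow(tr) > 2L)
    return("between 1 and 2 transitions are supported")
  if (!all(is.finite(tr$tm)) || any(tr$tm <= 0) || any(tr$tm >= 100))
    return("tm must be finite and within (0, 100) degrees C")
  if (!all(is.finite(tr$dh)) || any(abs(tr$dh) <= 0))
    return("|dh| must be finite and positive")
  if (any(tr$amplitude <= 0) || any(tr$amplitude > 1))
    return("amplitudes must lie in (0, 1]")
  if (abs(sum(tr$amplitude) - 1) > 1e-9)
    return("amplitudes must sum to 1 (within 1e-9)")
  if (is.unsorted(tr$tm)) return("transitions must be sorted by ascending tm")
  TRUE
}

#' @rdname UnfoldingModel
#' @export
setClass("UnfoldingModel",
  representation(transitions = "data.frame",
                 baselineFolded = "numeric",
                 baselineUnfolded = "numeric"),
  prototype(baselineFolded = c(0, 0), baselineUnfolded = c(1, 0)))

setValidity("UnfoldingModel", function(object) {
  msg <- .validTransitions(object@transitions)
  if (!isTRUE(msg)) return(msg)
  for (nm in c("baselineFolded", "baselineUnfolded")) {
    b <- slot(object, nm)
    if (length(b) != 2L || !all(is.finite(b)))
      return(sprintf("%s must be a finite (intercept, slope) pair", nm))
  }
  TRUE
})

#' Two-state van't Hoff unfolding model of a coiled coil
#'
#' Represents the thermal unfolding of an alpha-helical coiled coil as one
#' or a weighted sum of two independent two-state transitions, plus linear
#' folded and unfolded signal baselines. The model is shared by the melt
#' simulator and the curve fitters.
#'
#' @param transitions a transition table from [transitionTable()], or the
#'   arguments \code{tm}, \code{dh}, \code{amplitude} to build one.
#' @param baselineFolded,baselineUnfolded numeric \code{(intercept, slope)}
#'   pairs describing the raw CD signal of the fully folded and fully
#'   unfolded states as linear functions of temperature (degrees C).
#' @param tm,dh,amplitude passed to [transitionTable()] when
#'   \code{transitions} is missing.
#' @return an \code{UnfoldingModel} object.
#' @examples
#' wt <- UnfoldingModel(tm = 34.1, dh = -455.8)
#' fractionUnfolded(wt, c(30, 34.1, 38))
#' @aliases UnfoldingModel-class
#' @export
UnfoldingModel <- function(transitions = NULL, tm = NULL, dh = NULL,
                           amplitude = NULL,
                           baselineFolded = c(0, 0),
                           baselineUnfolded = c(1, 0)) {
  if (is.null(transitions)) {
    if (is.null(amplitude)) amplitude <- rep(1 / length(tm), length(tm))
    transitions <- transitionTable(tm, dh, amplitude)
  }
  new("UnfoldingModel", transitions = transitions,
      baselineFolded = as.numeric(baselineFolded),
      baselineUnfolded = as.numeric(baselineUnfolded))
}

#' Raw circular-dichroism melting trace
#'
#' A single thermal melt monitored at 222 nm: a strictly increasing
#' temperature grid with the CD signal (delta-absorbance or millidegrees)
#' and acquisition metadata (protein id, N-terminal acetylation state, salt
#' concentration, heating rate, replicate id).
#'
#' @aliases MeltCurve-class
#' @export
setClass("MeltCurve",
  representation(temperature = "numeric", signal = "numeric", meta = "list"))

setValidity("MeltCurve", function(object) {
  t <- object@temperature
  if (length(t) < 2L) return("a melt needs at least 2 points")
  if (any(!is.finite(t)) || any(diff(t) <= 0))
    return("temperature must be finite and strictly increasing")
  if (length(object@signal) != length(t) || any(!is.finite(object@signal)))
    return("signal must be finite and match the temperature grid")
  TRUE
})

#' @param temperature numeric temperature grid, degrees C. Rows are sorted
#'   and duplicate temperatures averaged.
#' @param signal numeric CD signal at 222 nm, same length.
#' @param meta named list of metadata (protein, acetylated, saltM,
#'   heatingRate, replicate).
#' @rdname MeltCurve-class
#' @export
MeltCurve <- function(temperature, signal, meta = list()) {
  o <- order(temperature)
  temperature <- as.numeric(temperature[o])
  signal <- as.numeric(signal[o])
  if (anyDuplicated(temperature)) {
    signal <- as.numeric(tapply(signal, temperature, mean))
    temperature <- sort(unique(temperature))
  }
  new("MeltCurve", temperature = temperature, signal = signal, meta = meta)
}

#' Melting trace expressed as fraction of unfolded protein
#'
#' The 222 nm trace rescaled to the unfolded fraction over a normalization
#' window (10-50 degrees C by default), carrying the source metadata.
#'
#' @aliases NormalizedMelt-class
#' @export
setClass("NormalizedMelt",
  representation(temperature = "numeric", fraction = "numeric",
                 window = "numeric", meta = "list"))

setValidity("NormalizedMelt", function(object) {
  if (length(object@fraction) != length(object@temperature))
    return("fraction and temperature lengths differ")
  if (any(object@fraction < -1e-12) || any(object@fraction > 1 + 1e-12))
    return("fraction must lie in [0, 1]")
  TRUE
})

#' Smoothed first derivative of an unfolding curve
#'
#' d(fraction)/dT on the melt's grid, computed after moving-average
#' smoothing; the substrate for Gaussian peak deconvolution.
#'
#' @aliases DerivativeCurve-class
#' @export
setClass("DerivativeCurve",
  representation(temperature = "numeric", dfdT = "numeric",
                 smoothingWindow = "numeric", meta = "list"))

#' Result of a one- or two-transition melt fit
#'
#' Holds the Gaussian deconvolution of the derivative curve (per-component
#' mean, sd and normalized area), the derived or directly fitted transition
#' table (tm, dh, amplitude), the residual sum of squares and the model
#' selection diagnostics.
#'
#' @aliases MeltFitResult-class
#' @export
setClass("MeltFitResult",
  representation(transitions = "data.frame", nComponents = "integer",
                 gaussians = "data.frame", rss = "numeric",
                 modelSelection = "list", flags = "character",
                 meta = "list"))

setValidity("MeltFitResult", function(object) {
  g <- object@gaussians
  if (nrow(g)) {
    if (any(g$area < 0)) return("gaussian areas must be non-negative")
    if (abs(sum(g$area) - 1) > 1e-6)
      return("gaussian areas must be normalized to sum to 1")
    if (is.unsorted(g$mean)) return("gaussian components must be sorted by mean")
  }
  TRUE
})

#' Co-sedimentation binding series
#'
#' One actin-tropomyosin co-sedimentation titration: fixed total actin,
#' ascending total tropomyosin, pellet band densities, and (once computed)
#' fractional saturation theta and free tropomyosin concentration.
#'
#' @aliases BindingSeries-class
#' @export
setClass("BindingSeries",
  representation(actinTotal = "numeric", tpmTotal = "numeric",
                 densityTpm = "numeric", densityActin = "numeric",
                 theta = "numeric", free = "numeric", meta = "list"))

setValidity("BindingSeries", function(object) {
  tt <- object@tpmTotal
  if (length(tt) < 5L) return("a binding series needs at least 5 points")
  if (any(diff(tt) <= 0)) return("tpmTotal must be strictly increasing")
  if (length(object@actinTotal) != 1L || object@actinTotal <= 0)
    return("actinTotal must be a single positive concentration")
  if (length(object@theta) && any(object@theta < -1e-9 | object@theta > 1 + 1e-9))
    return("theta must lie in [0, 1]")
  if (length(object@free) &&
      any(object@free < -1e-9 | object@free > tt + 1e-9))
    return("free must lie in [0, tpmTotal] pointwise")
  TRUE
})

#' @param actinTotal fixed total actin concentration, uM.
#' @param tpmTotal ascending total tropomyosin concentrations, uM.
#' @param densityTpm,densityActin pellet band densities (arbitrary units).
#' @param theta,free optional precomputed saturation / free concentration.
#' @param meta named list (acetylated, temperatureC, ...).
#' @rdname BindingSeries-class
#' @export
BindingSeries <- function(actinTotal, tpmTotal, densityTpm = numeric(),
                          densityActin = numeric(), theta = numeric(),
                          free = numeric(), meta = list()) {
  new("BindingSeries", actinTotal = as.numeric(actinTotal),
      tpmTotal = as.numeric(tpmTotal), densityTpm = as.numeric(densityTpm),
      densityActin = as.numeric(densityActin), theta = as.numeric(theta),
      free = as.numeric(free), meta = meta)
}

#' Hill-equation fit of a binding isotherm
#'
#' theta(free) = thetaMax * free^n / (k50^n + free^n): the half-saturation
#' constant \code{k50} (uM), Hill coefficient \code{nHill}, plateau
#' \code{thetaMax}, the standard error of k50 from the fit covariance, the
#' residual sum of squares, and the fitted curve.
#'
#' @aliases HillFit-class
#' @export
setClass("HillFit",
  representation(k50 = "numeric", nHill = "numeric", thetaMax = "numeric",
                 seK50 = "numeric", rss = "numeric", curve = "data.frame",
                 flags = "character"))

setValidity("HillFit", function(object) {
  if (object@k50 <= 0) return("k50 must be positive")
  if (object@nHill <= 0) return("the Hill coefficient must be positive")
  if (object@thetaMax <= 0 || object@thetaMax > 1.05)
    return("thetaMax must lie in (0, 1.05]")
  TRUE
})

#' Heptad register annotation of a coiled-coil sequence
#'
#' Per-residue a-g register letters propagated from user-supplied anchors,
#' together with the segment structure (each segment carries one contiguous
#' register).
#'
#' @aliases HeptadAnnotation-class
#' @export
setClass("HeptadAnnotation",
  representation(sequence = "character", letters = "character",
                 segments = "data.frame"))

setValidity("HeptadAnnotation", function(object) {
  n <- nchar(object@sequence)
  if (length(object@letters) != n)
    return("letters must have one entry per residue")
  if (!all(object@letters %in% .HEPTAD))
    return("letters must be heptad positions a-g")
  seg <- object@segments
  if (any(seg$start > seg$end)) return("segment start must not exceed end")
  covered <- sort(unlist(Map(seq, seg$start, seg$end)))
  if (!identical(covered, seq_len(n)))
    return("segments must tile the sequence without overlap")
  TRUE
})

#' Report on a single coiled-coil point substitution
#'
#' The heptad letter of the mutated position, the residue-class change, the
#' charge-pair interactions gained, lost or flipped, and a structural
#' category (core-packing for a/d positions, intra-helix-pair,
#' interchain-bridge, or surface).
#'
#' @aliases MutationReport-class
#' @export
setClass("MutationReport",
  representation(position = "integer", wtAa = "character", mutAa = "character",
                 letter = "character", classification = "character",
                 classChange = "character", pairsBefore = "data.frame",
                 pairsAfter = "data.frame", notes = "character"))
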