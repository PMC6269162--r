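#' Accessors for coilmelt objects
#'
#' Small accessor generics: \code{transitions()} returns the transition
#' table (tm, dh, amplitude); \code{temperature()} the temperature grid;
#' \code{cdSignal()} the raw CD signal; \code{fraction()} the unfolded
#' fraction; \code{dfdT()} the derivative values; \code{gaussians()} the
#' Gaussian component table; \code{nComponents()} the selected number of
#' transitions; \code{fitRSS()} the residual sum of squares; \code{k50()},
#' \code{nHill()}, \code{thetaMax()} the Hill parameters;
#' \code{registerLetters()} the per-residue heptad letters.
#'
#' @param object a coilmelt S4 object.
#' @return the slot value described above.
#' @name accessors
#' @examples
#' m <- UnfoldingModel(tm = 34.1, dh = -455.8)
#' transitions(m)
NULL

#' @rdname accessors
#' @export
setGeneric("transitions", function(object) standardGeneric("transitions"))
#' @rdname accessors
#' @export
setGeneric("temperature", function(object) standardGeneric("temperature"))
#' @rdname accessors
#' @export
setGeneric("cdSignal", function(object) standardGeneric("cdSignal"))
#' @rdname accessors
#' @export
setGeneric("fraction", function(object) standardGeneric("fraction"))
#' @rdname accessors
#' @export
setGeneric("dfdT", function(object) standardGeneric("dfdT"))
#' @rdname accessors
#' @export
setGeneric("gaussians", function(object) standardGeneric("gaussians"))
#' @rdname accessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))
#' @rdname accessors
#' @export
setGeneric("fitRSS", function(object) standardGeneric("fitRSS"))
#' @rdname accessors
#' @export
setGeneric("k50", function(object) standardGeneric("k50"))
#' @rdname accessors
#' @export
setGeneric("nHill", function(object) standardGeneric("nHill"))
#' @rdname accessors
#' @export
setGeneric("thetaMax", function(object) standardGeneric("thetaMax"))
#' @rdname accessors
#' @export
setGeneric("registerLetters", function(object) standardGeneric("registerLetters"))

#' @rdname accessors
#' @export
setMethod("transitions", "UnfoldingModel", function(object) object@transitions)
#' @rdname accessors
#' @export
setMethod("transitions", "MeltFitResult", function(object) object@transitions)
#' @rdname accessors
#' @export
setMethod("temperature", "MeltCurve", function(object) object@temperature)
#' @rdname accessors
#' @export
setMethod("temperature", "NormalizedMelt", function(object) object@temperature)
#' @rdname accessors
#' @export
setMethod("temperature", "DerivativeCurve", function(object) object@temperature)
#' @rdname accessors
#' @export
setMethod("cdSignal", "MeltCurve", function(object) object@signal)
#' @rdname accessors
#' @export
setMethod("fraction", "NormalizedMelt", function(object) object@fraction)
#' @rdname accessors
#' @export
setMethod("dfdT", "DerivativeCurve", function(object) object@dfdT)
#' @rdname accessors
#' @export
setMethod("gaussians", "MeltFitResult", function(object) object@gaussians)
#' @rdname accessors
#' @export
setMethod("nComponents", "MeltFitResult", function(object) object@nComponents)
#' @rdname accessors
#' @export
setMethod("fitRSS", "MeltFitResult", function(object) object@rss)
#' @rdname accessors
#' @export
setMethod("fitRSS", "HillFit", function(object) object@rss)
#' @rdname accessors
#' @export
setMethod("k50", "HillFit", function(object) object@k50)
#' @rdname accessors
#' @export
setMethod("nHill", "HillFit", function(object) object@nHill)
#' @rdname accessors
#' @export
setMethod("thetaMax", "HillFit", function(object) object@thetaMax)
#' @rdname accessors
#' @export
setMethod("registerLetters", "HeptadAnnotation", function(object) object@letters)

setMethod("show", "UnfoldingModel", function(object) {
  tr <- object@transitions
  cat(sprintf("UnfoldingModel with %d transition(s)\n", nrow(tr)))
  for (i in seq_len(nrow(tr)))
    cat(sprintf("  Tm = %.1f C, dH = %.1f kJ/mol, amplitude = %.2f\n",
                tr$tm[i], -abs(tr$dh[i]), tr$amplitude[i]))
  invisible(object)
})

setMethod("show", "MeltCurve", function(object) {
  cat(sprintf("MeltCurve: %d points, %.1f-%.1f C", length(object@temperature),
              min(object@temperature), max(object@temperature)))
  if (!is.null(object@meta$protein))
    cat(sprintf(" [%s%s]", object@meta$protein,
                if (isTRUE(object@meta$acetylated)) ", Nt-acetylated" else ""))
  cat("\n")
  invisible(object)
})

setMethod("show", "MeltFitResult", function(object) {
  cat(sprintf("MeltFitResult: %d component(s), rss = %.3g\n",
              object@nComponents, object@rss))
  tr <- object@transitions
  for (i in seq_len(nrow(tr)))
    cat(sprintf("  Tm = %.1f C, dH = %.1f kJ/mol, amplitude = %.2f\n",
                tr$tm[i], -abs(tr$dh[i]), tr$amplitude[i]))
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "BindingSeries", function(object) {
  cat(sprintf("BindingSeries: %d points, actin %.1f uM, Tpm %.2f-%.2f uM\n",
              length(object@tpmTotal), object@actinTotal,
              min(object@tpmTotal), max(object@tpmTotal)))
  invisible(object)
})

setMethod("show", "HillFit", function(object) {
  cat(sprintf("HillFit: K50 = %.2f +/- %.2f uM, n = %.2f, thetaMax = %.2f\n",
              object@k50, object@seK50, object@nHill, object@thetaMax))
  invisible(object)
})

setMethod("show", "HeptadAnnotation", function(object) {
  n <- nchar(object@sequence)
  cat(sprintf("HeptadAnnotation: %d residues, %d segment(s)\n", n,
              nrow(object@segments)))
  k <- min(n, 28L)
  cat("  ", substr(object@sequence, 1, k), if (n > k) "...", "\n", sep = "")
  cat("  ", paste(object@letters[seq_len(k)], collapse = ""),
      if (n > k) "...", "\n", sep = "")
  invisible(object)
})

setMethod("show", "MutationReport", function(object) {
  cat(sprintf("MutationReport: %s%d%s (heptad %s) -> %s\n", object@wtAa,
              object@position, object@mutAa, object@letter,
              object@classification))
  if (length(object@notes)) cat(" ", paste(object@notes, collapse = "\n  "), "\n")
  invisible(object)
})
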