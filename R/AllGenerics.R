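## Generics and accessors.

#' Derived conformational constant of the protonated protein
#'
#' K_H is fixed by cycle closure: K_D/K_H must equal Ka(open)/Ka(closed),
#' so K_H = K_D * 10^(pkaOpen - pkaClosed).
#'
#' @param object A [CycleParameters-class] object.
#' @return The conformational equilibrium constant K_H (dimensionless).
#' @examples
#' kH(CycleParameters(4.3, 8.5, 100))  # NP4 reference cycle: 100 * 10^-4.2
#' @export
setGeneric("kH", function(object) standardGeneric("kH"))

#' Apparent pKa of the proton-linked closed-open transition
#'
#' @param object A [CycleParameters-class] object.
#' @return The apparent pKa (dimensionless).
#' @export
setGeneric("apparentPKa", function(object) standardGeneric("apparentPKa"))

#' Effective bimolecular binding rate constant
#'
#' @param object A [MicroRates-class] object.
#' @return Effective k_on in M^-1 s^-1.
#' @export
setGeneric("effectiveKon", function(object) standardGeneric("effectiveKon"))

#' Accessors for kinetic and spectral objects
#'
#' `curveTimes`, `curveFraction` and `noiseSigma` extract the axes of a
#' [ProgressCurve-class]; `wavelengths`, `delays` and `deltaA` those of a
#' [TAMap-class]; `singularValues`, `spectralComponents`,
#' `temporalAmplitudes` and `rankSelected` the parts of an
#' [SVDResult-class]; `lifetimeGrid` and `amplitudes` those of a
#' [LifetimeDistribution-class]; `rates` the named rate vector of a
#' [MicroRates-class] or the best-fit rates of a [FitResult-class].
#'
#' @param object The object to access.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("curveTimes", function(object) standardGeneric("curveTimes"))
#' @rdname accessors
#' @export
setGeneric("curveFraction", function(object) standardGeneric("curveFraction"))
#' @rdname accessors
#' @export
setGeneric("noiseSigma", function(object) standardGeneric("noiseSigma"))
#' @rdname accessors
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setGeneric("delays", function(object) standardGeneric("delays"))
#' @rdname accessors
#' @export
setGeneric("deltaA", function(object) standardGeneric("deltaA"))
#' @rdname accessors
#' @export
setGeneric("singularValues",
           function(object) standardGeneric("singularValues"))
#' @rdname accessors
#' @export
setGeneric("spectralComponents",
           function(object) standardGeneric("spectralComponents"))
#' @rdname accessors
#' @export
setGeneric("temporalAmplitudes",
           function(object) standardGeneric("temporalAmplitudes"))
#' @rdname accessors
#' @export
setGeneric("rankSelected", function(object) standardGeneric("rankSelected"))
#' @rdname accessors
#' @export
setGeneric("lifetimeGrid", function(object) standardGeneric("lifetimeGrid"))
#' @rdname accessors
#' @export
setGeneric("amplitudes", function(object) standardGeneric("amplitudes"))
#' @rdname accessors
#' @export
setGeneric("rates", function(object) standardGeneric("rates"))

#' @rdname accessors
setMethod("curveTimes", "ProgressCurve", function(object) object@times)
#' @rdname accessors
setMethod("curveFraction", "ProgressCurve", function(object) object@fraction)
#' @rdname accessors
setMethod("noiseSigma", "ProgressCurve", function(object) object@sigma)
#' @rdname accessors
setMethod("wavelengths", "TAMap", function(object) object@wavelengths)
#' @rdname accessors
setMethod("delays", "TAMap", function(object) object@delays)
#' @rdname accessors
setMethod("deltaA", "TAMap", function(object) object@deltaA)
#' @rdname accessors
setMethod("singularValues", "SVDResult", function(object) object@d)
#' @rdname accessors
setMethod("spectralComponents", "SVDResult", function(object) object@u)
#' @rdname accessors
setMethod("temporalAmplitudes", "SVDResult", function(object) object@v)
#' @rdname accessors
setMethod("rankSelected", "SVDResult", function(object) object@rankSelected)
#' @rdname accessors
setMethod("lifetimeGrid", "LifetimeDistribution",
          function(object) object@log10Tau)
#' @rdname accessors
setMethod("amplitudes", "LifetimeDistribution",
          function(object) object@amplitude)
#' @rdname accessors
setMethod("rates", "MicroRates", function(object) object@rates)
#' @rdname accessors
setMethod("rates", "FitResult", function(object) object@rates@rates)
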