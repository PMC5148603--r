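#' Peaks of an isotope envelope
#'
#' @param x an [IsotopeEnvelope-class] or [SyntheticSpectrum-class].
#' @return data.frame with columns `mass` (Da) and `abundance`.
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @describeIn peaks sticks of an envelope
setMethod("peaks", "IsotopeEnvelope", function(x)
  data.frame(mass = x@mass, abundance = x@abundance))

#' @describeIn peaks sticks of the embedded envelope
setMethod("peaks", "SyntheticSpectrum", function(x) peaks(x@envelope))

#' Abundance-weighted mean (centroid) mass of an envelope
#'
#' The average mass of a (possibly bimodal) isotope envelope; deuterium
#' uptake is the shift of this centroid relative to an undeuterated
#' reference.
#'
#' @param x an [IsotopeEnvelope-class] or [SyntheticSpectrum-class].
#' @return numeric centroid mass in Da.
#' @examples
#' centroidMass(IsotopeEnvelope(c(10, 20), c(0.5, 0.5), normalized = TRUE))
#' @export
setGeneric("centroidMass", function(x) standardGeneric("centroidMass"))

#' @describeIn centroidMass centroid of an envelope
setMethod("centroidMass", "IsotopeEnvelope", function(x) {
  if (!length(x@mass)) stop("cannot take the centroid of an empty envelope")
  s <- sum(x@abundance)
  if (s <= 0) stop("cannot take the centroid of an all-zero envelope")
  sum(x@mass * x@abundance) / s
})

#' @describeIn centroidMass centroid of the embedded envelope
setMethod("centroidMass", "SyntheticSpectrum", function(x)
  centroidMass(x@envelope))

#' Unfolded fraction carried by a fit
#'
#' @param x a [BimodalFit-class].
#' @return numeric fraction in [0,1], or `NA` for ambiguous or
#'   non-converged fits.
#' @export
setGeneric("unfoldedFraction", function(x) standardGeneric("unfoldedFraction"))

#' @describeIn unfoldedFraction area-ratio fraction of a fit
setMethod("unfoldedFraction", "BimodalFit", function(x) x@unfoldedFraction)

#' Envelope accessor for simulated spectra
#'
#' @param x a [SyntheticSpectrum-class].
#' @return the embedded [IsotopeEnvelope-class].
#' @export
setGeneric("envelope", function(x) standardGeneric("envelope"))

#' @describeIn envelope the raw-intensity envelope of a spectrum
setMethod("envelope", "SyntheticSpectrum", function(x) x@envelope)

#' Points of a time course
#'
#' @param x a [TimeCourse-class].
#' @return data.frame with columns `time`, `fraction`, `sd`, `n`, `flags`.
#' @export
setGeneric("coursePoints", function(x) standardGeneric("coursePoints"))

#' @describeIn coursePoints aggregated points of the course
setMethod("coursePoints", "TimeCourse", function(x) x@points)

#' Condition metadata of a time course
#'
#' @param x a [TimeCourse-class].
#' @return named list with elements such as `inhibitor`, `inhibitorConc`,
#'   `substrateConc`, `protectant`.
#' @export
setGeneric("courseCondition", function(x) standardGeneric("courseCondition"))

#' @describeIn courseCondition condition metadata list
setMethod("courseCondition", "TimeCourse", function(x) x@condition)
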