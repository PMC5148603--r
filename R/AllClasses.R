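#' @import methods
NULL

#' IsotopeEnvelope: a stick spectrum in neutral-mass space
#'
#' An isotope envelope is an ordered set of (neutral mass, abundance)
#' sticks describing the isotopologue distribution of one peptide state
#' or a mixture of states. Envelopes live in neutral-mass coordinates;
#' conversion to m/z is an explicit boundary operation ([toMz()]).
#'
#' @slot mass numeric, strictly increasing neutral masses (Da).
#' @slot abundance numeric, nonnegative relative abundances.
#' @slot normalized logical; when `TRUE` the abundances sum to 1 (within
#'   1e-9).
#' @slot flags character vector of quality flags (e.g. `"degenerate"`).
#'
#' @seealso [IsotopeEnvelope()], [centroidMass()], [normalizeEnvelope()]
#' @exportClass IsotopeEnvelope
setClass("IsotopeEnvelope",
  representation(mass = "numeric", abundance = "numeric",
                 normalized = "logical", flags = "character"),
  prototype(mass = numeric(), abundance = numeric(),
            normalized = FALSE, flags = character()))

setValidity("IsotopeEnvelope", function(object) {
  msg <- character()
  if (length(object@mass) != length(object@abundance))
    msg <- c(msg, "mass and abundance must have equal length")
  if (any(object@abundance < 0))
    msg <- c(msg, "abundances must be nonnegative")
  if (length(object@mass) > 1 && any(diff(object@mass) <= 0))
    msg <- c(msg, "masses must be strictly increasing")
  if (isTRUE(object@normalized) && length(object@abundance) &&
      abs(sum(object@abundance) - 1) > 1e-9)
    msg <- c(msg, "normalized envelope abundances must sum to 1 (+/- 1e-9)")
  if (length(msg)) msg else TRUE
})

#' Construct an isotope envelope
#'
#' @param mass numeric vector of neutral masses (Da); need not be sorted,
#'   sticks are ordered on construction.
#' @param abundance numeric vector of nonnegative abundances.
#' @param normalized logical, whether `abundance` already sums to 1.
#' @param flags character vector of quality flags.
#' @return An [IsotopeEnvelope-class] object.
#' @examples
#' env <- IsotopeEnvelope(c(1000, 1001), c(0.7, 0.3), normalized = TRUE)
#' centroidMass(env)
#' @export
IsotopeEnvelope <- function(mass, abundance, normalized = FALSE,
                            flags = character()) {
  o <- order(mass)
  new("IsotopeEnvelope", mass = as.numeric(mass[o]),
      abundance = as.numeric(abundance[o]),
      normalized = isTRUE(normalized), flags = flags)
}

setMethod("show", "IsotopeEnvelope", function(object) {
  n <- length(object@mass)
  cat("IsotopeEnvelope with", n, "peaks",
      if (object@normalized) "(normalized)" else "(raw intensities)", "\n")
  if (n) {
    cat(sprintf("  mass range: %.4f - %.4f Da\n",
                min(object@mass), max(object@mass)))
    cat(sprintf("  centroid:   %.4f Da\n", centroidMass(object)))
  }
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' PeptideSpec: a peptide definition
#'
#' Describes one (typically peptic) peptide by protein id and 1-based
#' inclusive residue coordinates in mature-protein numbering. The
#' sequence and charge are optional; when the sequence is unknown (as
#' for peptides whose identity is not published) an averagine stand-in
#' composition at `massDa` is used for envelope synthesis.
#'
#' @slot protein character, protein identifier.
#' @slot start,end integer residue coordinates (1-based, inclusive).
#' @slot sequence character amino-acid sequence or `NA`.
#' @slot charge integer charge state or `NA`.
#' @slot nExchangeable integer count of exchange-competent backbone
#'   amides, or `NA` to derive it from the sequence.
#' @slot plusMet logical; `TRUE` when the observed peptide carries an
#'   initiator methionine that is excluded from the residue numbering.
#' @slot massDa numeric; approximate neutral mass used for the averagine
#'   stand-in when no sequence is available.
#' @exportClass PeptideSpec
setClass("PeptideSpec",
  representation(protein = "character", start = "integer", end = "integer",
                 sequence = "character", charge = "integer",
                 nExchangeable = "integer", plusMet = "logical",
                 massDa = "numeric"))

setValidity("PeptideSpec", function(object) {
  msg <- character()
  len <- object@end - object@start + 1L
  if (object@start < 1L) msg <- c(msg, "start must be >= 1")
  if (object@start > object@end) msg <- c(msg, "start must be <= end")
  if (!is.na(object@sequence) && nchar(object@sequence) != len)
    msg <- c(msg, sprintf("sequence length %d != end - start + 1 = %d",
                          nchar(object@sequence), len))
  if (!is.na(object@charge) && object@charge < 1L)
    msg <- c(msg, "charge must be a positive integer")
  if (!is.na(object@nExchangeable) &&
      (object@nExchangeable < 0L || object@nExchangeable > len - 1L))
    msg <- c(msg, "nExchangeable must be in [0, length - 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a peptide definition
#'
#' @param protein protein identifier.
#' @param start,end 1-based inclusive residue coordinates
#'   (mature-protein numbering).
#' @param sequence optional amino-acid sequence (length must equal
#'   `end - start + 1`).
#' @param charge optional positive integer charge state.
#' @param nExchangeable optional override for the number of
#'   exchange-competent backbone amides; when `NA` and a sequence is
#'   given it is derived with [nExchangeableAmides()].
#' @param plusMet logical, observed peptide carries an extra initiator
#'   methionine not counted in the residue numbering.
#' @param massDa approximate neutral mass (Da) used for an averagine
#'   stand-in composition when `sequence` is `NA`.
#' @return A [PeptideSpec-class] object.
#' @examples
#' PeptideSpec("LPL", 131, 165, nExchangeable = 31, massDa = 3800)
#' @export
PeptideSpec <- function(protein, start, end, sequence = NA_character_,
                        charge = NA_integer_, nExchangeable = NA_integer_,
                        plusMet = FALSE, massDa = NA_real_) {
  if (is.na(nExchangeable) && !is.na(sequence))
    nExchangeable <- nExchangeableAmides(sequence)
  new("PeptideSpec", protein = as.character(protein),
      start = as.integer(start), end = as.integer(end),
      sequence = as.character(sequence), charge = as.integer(charge),
      nExchangeable = as.integer(nExchangeable), plusMet = isTRUE(plusMet),
      massDa = as.numeric(massDa))
}

setMethod("show", "PeptideSpec", function(object) {
  cat(sprintf("PeptideSpec %s %d-%d%s\n", object@protein, object@start,
              object@end, if (object@plusMet) " (+1 Met)" else ""))
  if (!is.na(object@sequence)) cat("  sequence:", object@sequence, "\n")
  if (!is.na(object@nExchangeable))
    cat("  exchangeable amides:", object@nExchangeable, "\n")
})

#' SyntheticSpectrum: one simulated replicate envelope with metadata
#'
#' @slot envelope an [IsotopeEnvelope-class] carrying raw (noisy,
#'   un-normalized) intensities.
#' @slot peptide the [PeptideSpec-class] the spectrum belongs to.
#' @slot replicate integer replicate index.
#' @slot timeMin numeric incubation time in minutes.
#' @slot preset character preset name the spectrum was generated from.
#' @slot metadata named list of condition metadata (concentrations,
#'   protectant, labeling parameters, seed lineage).
#' @exportClass SyntheticSpectrum
setClass("SyntheticSpectrum",
  representation(envelope = "IsotopeEnvelope", peptide = "PeptideSpec",
                 replicate = "integer", timeMin = "numeric",
                 preset = "character", metadata = "list"))

setValidity("SyntheticSpectrum", function(object) {
  if (any(object@envelope@abundance < 0))
    "intensities must be nonnegative" else TRUE
})

setMethod("show", "SyntheticSpectrum", function(object) {
  cat(sprintf("SyntheticSpectrum [%s] rep %d, t = %g min\n",
              object@preset, object@replicate, object@timeMin))
  cat(sprintf("  %d peaks, centroid %.3f Da\n",
              length(object@envelope@mass), centroidMass(object@envelope)))
})

#' BimodalFit: two-Gaussian decomposition of an isotope envelope
#'
#' @slot model character, `"unimodal"` or `"bimodal"` (selected model).
#' @slot components data.frame with one row per fitted Gaussian
#'   (columns `centroid`, `sigma`, `amplitude`, `area`), ordered folded
#'   first (lower centroid).
#' @slot unfoldedFraction numeric in [0,1], or `NA` when ambiguous or
#'   not converged.
#' @slot residual numeric residual sum of squares of the selected model.
#' @slot bic numeric named vector with elements `unimodal`, `bimodal`.
#' @slot converged logical.
#' @slot ambiguous logical; `TRUE` when a unimodal envelope sits between
#'   the folded and unfolded references.
#' @slot flags character vector of diagnostic flags.
#' @exportClass BimodalFit
setClass("BimodalFit",
  representation(model = "character", components = "data.frame",
                 unfoldedFraction = "numeric", residual = "numeric",
                 bic = "numeric", converged = "logical",
                 ambiguous = "logical", flags = "character"),
  prototype(model = "unimodal",
            components = data.frame(centroid = numeric(),
                                    sigma = numeric(),
                                    amplitude = numeric(),
                                    area = numeric()),
            unfoldedFraction = NA_real_, residual = NA_real_,
            bic = c(unimodal = NA_real_, bimodal = NA_real_),
            converged = FALSE, ambiguous = FALSE, flags = character()))

setValidity("BimodalFit", function(object) {
  msg <- character()
  if (!object@model %in% c("unimodal", "bimodal"))
    msg <- c(msg, "model must be 'unimodal' or 'bimodal'")
  cmp <- object@components
  if (nrow(cmp)) {
    if (any(cmp$sigma <= 0)) msg <- c(msg, "component sigma must be > 0")
    if (any(cmp$amplitude < 0)) msg <- c(msg, "amplitude must be >= 0")
    bad <- abs(cmp$area - cmp$amplitude * cmp$sigma * sqrt(2 * pi)) >
      1e-9 * pmax(cmp$area, 1)
    if (any(bad)) msg <- c(msg, "area inconsistent with amplitude * sigma * sqrt(2*pi)")
    if (nrow(cmp) == 2 && diff(cmp$centroid) <= 0)
      msg <- c(msg, "folded component must have the lower centroid")
  }
  f <- object@unfoldedFraction
  if (!is.na(f) && (f < 0 || f > 1))
    msg <- c(msg, "unfoldedFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BimodalFit", function(object) {
  cat(sprintf("BimodalFit: %s model%s\n", object@model,
              if (!object@converged) " (NOT converged)" else ""))
  if (nrow(object@components)) {
    print(round(object@components, 4))
  }
  cat("  unfolded fraction:",
      if (is.na(object@unfoldedFraction)) "NA"
      else sprintf("%.4f", object@unfoldedFraction), "\n")
  if (object@ambiguous) cat("  ambiguous unimodal assignment\n")
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

#' TimeCourse: fraction unfolded versus time for one condition
#'
#' @slot condition named list of condition metadata (`inhibitor`,
#'   `inhibitorConc` in uM, `substrateConc` in uM, `protectant`).
#' @slot points data.frame with columns `time` (min), `fraction`, `sd`,
#'   `n`, `flags`.
#' @exportClass TimeCourse
setClass("TimeCourse",
  representation(condition = "list", points = "data.frame"))

setValidity("TimeCourse", function(object) {
  msg <- character()
  p <- object@points
  need <- c("time", "fraction", "sd", "n")
  if (!all(need %in% names(p)))
    msg <- c(msg, "points must have columns time, fraction, sd, n")
  else {
    if (any(diff(p$time) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    ok <- is.na(p$fraction) | (p$fraction >= 0 & p$fraction <= 1)
    if (!all(ok)) msg <- c(msg, "fractions must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TimeCourse", function(object) {
  cond <- object@condition
  cat("TimeCourse:",
      if (!is.null(cond$inhibitor)) paste0(cond$inhibitor, " "),
      if (!is.null(cond$inhibitorConc))
        sprintf("[%g uM] ", cond$inhibitorConc), "\n", sep = "")
  print(round(object@points[c("time", "fraction", "sd", "n")], 4))
})

#' RateEstimate: through-origin initial unfolding rate for one condition
#'
#' @slot rate numeric, fraction unfolded per minute (`NA` when withheld).
#' @slot stderr numeric standard error of the rate.
#' @slot molarRate numeric, uM per minute (`rate * substrateConc`).
#' @slot substrateConc numeric, uM.
#' @slot included data.frame of (time, fraction) points used.
#' @slot excluded data.frame of excluded points with a `reason` column.
#' @slot condition named list of condition metadata.
#' @exportClass RateEstimate
setClass("RateEstimate",
  representation(rate = "numeric", stderr = "numeric",
                 molarRate = "numeric", substrateConc = "numeric",
                 included = "data.frame", excluded = "data.frame",
                 condition = "list"))

setValidity("RateEstimate", function(object) {
  msg <- character()
  if (!is.na(object@rate) &&
      abs(object@molarRate - object@rate * object@substrateConc) > 1e-12)
    msg <- c(msg, "molarRate must equal rate * substrateConc")
  if (nrow(object@excluded) && !"reason" %in% names(object@excluded))
    msg <- c(msg, "excluded points must carry a reason column")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RateEstimate", function(object) {
  if (is.na(object@rate)) {
    cat("RateEstimate: withheld (",
        paste(unique(object@excluded$reason), collapse = ", "), ")\n",
        sep = "")
  } else {
    cat(sprintf(
      "RateEstimate: %.4f min^-1 (%.4f uM/min), SE %.4f, %d points used, %d excluded\n",
      object@rate, object@molarRate, object@stderr,
      nrow(object@included), nrow(object@excluded)))
  }
})

#' EfficacyEstimate: catalytic unfolding efficacy from a rate-vs-dose line
#'
#' The efficacy is the slope of the molar unfolding rate (uM/min) on
#' inhibitor concentration (uM): substrate molecules unfolded per
#' inhibitor molecule per minute.
#'
#' @slot efficacy numeric slope (free-intercept fit, primary estimate).
#' @slot stderr numeric standard error of the slope.
#' @slot intercept numeric fitted intercept (uM/min).
#' @slot rsquared numeric coefficient of determination.
#' @slot throughOrigin numeric secondary slope with the intercept fixed
#'   at zero.
#' @slot rates list of per-concentration [RateEstimate-class] inputs.
#' @slot table data.frame of (inhibitorConc, molarRate) pairs used.
#' @exportClass EfficacyEstimate
setClass("EfficacyEstimate",
  representation(efficacy = "numeric", stderr = "numeric",
                 intercept = "numeric", rsquared = "numeric",
                 throughOrigin = "numeric", rates = "list",
                 table = "data.frame"))

setMethod("show", "EfficacyEstimate", function(object) {
  cat(sprintf(
    "EfficacyEstimate: %.3f +/- %.3f substrate molecules per inhibitor per min\n",
    object@efficacy, object@stderr))
  cat(sprintf("  intercept %.4f uM/min, R^2 %.4f, through-origin slope %.3f\n",
              object@intercept, object@rsquared, object@throughOrigin))
  cat(sprintf("  based on %d concentrations\n", nrow(object@table)))
})
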