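## Peptide-level helpers built on the envelope arithmetic.

#' The diagnostic hydrolase-domain peptide
#'
#' Default stand-in for the peptic reporter peptide spanning residues
#' 131-165 of the LPL hydrolase domain, whose envelope bimodality
#' reports cooperative unfolding. Its sequence is not published, so an
#' averagine composition at 3800 Da with 31 exchange-competent amides
#' (35 residues) is used; only the envelope geometry matters for
#' fraction recovery, and every value is configurable through
#' [PeptideSpec()].
#'
#' @return a [PeptideSpec-class].
#' @export
diagnosticPeptide <- function() {
  PeptideSpec("LPL", 131L, 165L, nExchangeable = 31L, massDa = 3800)
}

#' Elemental composition backing a peptide definition
#'
#' Uses the real sequence when present, otherwise the averagine
#' stand-in at the peptide's nominal mass.
#'
#' @param peptide a [PeptideSpec-class].
#' @return named integer vector of element counts.
#' @export
peptideComposition <- function(peptide) {
  stopifnot(is(peptide, "PeptideSpec"))
  if (!is.na(peptide@sequence))
    return(compositionFromSequence(peptide@sequence))
  if (is.na(peptide@massDa))
    stop("peptide has neither a sequence nor a nominal mass")
  averagineComposition(peptide@massDa)
}

#' Exchange-competent amide count of a peptide
#'
#' @param peptide a [PeptideSpec-class].
#' @return integer count (explicit override, or derived from the
#'   sequence).
#' @export
peptideExchangeable <- function(peptide) {
  stopifnot(is(peptide, "PeptideSpec"))
  if (!is.na(peptide@nExchangeable)) return(peptide@nExchangeable)
  if (!is.na(peptide@sequence)) return(nExchangeableAmides(peptide@sequence))
  stop("peptide has neither an explicit nExchangeable nor a sequence")
}

#' Reference centroids for the folded and unfolded states
#'
#' Computes the noiseless centroid masses of the folded-state envelope
#' (partial EX2 incorporation at `pFolded`) and of the fully exchanged
#' unfolded-state envelope (incorporation at the D2O fraction). These
#' anchor the constrained two-Gaussian deconvolution.
#'
#' @param peptide a [PeptideSpec-class].
#' @param labeling a [labelingCondition()] list.
#' @param pFolded folded-state incorporation probability (must be below
#'   the D2O fraction so the two states are separable).
#' @return named numeric vector `c(folded = , unfolded = )` in Da.
#' @export
referenceCentroids <- function(peptide = diagnosticPeptide(),
                               labeling = labelingCondition(),
                               pFolded = 0.25) {
  st <- referenceStates(peptide, labeling, pFolded)
  c(folded = st$centroid[1], unfolded = st$centroid[2])
}

#' Reference centroids and widths of the pure folded/unfolded states
#'
#' Like [referenceCentroids()] but also returns the standard deviation
#' (square root of the second central moment) of each noiseless
#' pure-state envelope. The widths anchor the per-component width
#' windows of the constrained two-Gaussian fit, the same way the
#' centroids anchor its position windows.
#'
#' @inheritParams referenceCentroids
#' @return data.frame with columns `state` (`"folded"`, `"unfolded"`),
#'   `centroid` (Da) and `width` (Da).
#' @export
referenceStates <- function(peptide = diagnosticPeptide(),
                            labeling = labelingCondition(),
                            pFolded = 0.25) {
  nat <- naturalEnvelope(peptideComposition(peptide))
  nex <- peptideExchangeable(peptide)
  one <- function(p) {
    e <- applyDeuteration(nat, nex, p)
    mu <- centroidMass(e)
    c(mu, sqrt(sum(e@abundance * (e@mass - mu)^2) / sum(e@abundance)))
  }
  f <- one(pFolded); u <- one(labeling$d2oFraction)
  data.frame(state = c("folded", "unfolded"),
             centroid = c(f[1], u[1]), width = c(f[2], u[2]))
}
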