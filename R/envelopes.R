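## Isotope-envelope arithmetic: elemental compositions, natural isotopic
## distributions, binomial deuteration, mixtures and coordinate changes.

#' Elemental composition of a free peptide
#'
#' Sums the residue compositions of a peptide sequence and adds one
#' water (the free-peptide termini). Only the 20 standard one-letter
#' amino-acid codes are accepted.
#'
#' @param sequence nonempty amino-acid string.
#' @return named integer vector with elements C, H, N, O, S.
#' @examples
#' compositionFromSequence("G")   # C2 H5 N O2 (glycine + water)
#' @export
compositionFromSequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence) ||
      !nzchar(sequence))
    stop("sequence must be a nonempty string")
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!aa %in% rownames(.RESIDUE_COMPOSITION))
  if (length(bad))
    stop(sprintf("unknown amino-acid letter '%s' at position %d",
                 aa[bad[1]], bad[1]))
  comp <- colSums(.RESIDUE_COMPOSITION[aa, , drop = FALSE])
  comp["H"] <- comp["H"] + 2  # + H2O
  comp["O"] <- comp["O"] + 1
  storage.mode(comp) <- "integer"
  comp
}

#' Averagine stand-in composition for a target mass
#'
#' Scales the averagine unit (the average elemental composition per
#' residue of a typical protein, unit mass 111.1254 Da) to the target
#' mass, rounds C/N/O/S to integers and adjusts the hydrogen count so
#' the average mass lands as close as possible to the target. Used when
#' a peptide's sequence is unknown but its envelope geometry is needed.
#'
#' @param targetMass positive neutral mass in Da.
#' @return named integer vector with elements C, H, N, O, S.
#' @examples
#' averagineComposition(3800)
#' @export
averagineComposition <- function(targetMass) {
  if (!is.numeric(targetMass) || length(targetMass) != 1 ||
      is.na(targetMass) || targetMass <= 0)
    stop("targetMass must be a single positive number")
  n <- targetMass / .AVERAGINE_MASS
  comp <- round(n * .AVERAGINE_UNIT)
  heavy <- c("C", "N", "O", "S")
  rem <- targetMass - sum(comp[heavy] * .AVG_MASS[heavy])
  comp["H"] <- max(0, round(rem / .AVG_MASS["H"]))
  comp <- comp[c("C", "H", "N", "O", "S")]
  storage.mode(comp) <- "integer"
  comp
}

#' Average molecular mass of a composition
#'
#' @param composition named integer vector (C, H, N, O, S counts).
#' @return numeric average mass in Da.
#' @export
averageMass <- function(composition) {
  composition <- .checkComposition(composition)
  sum(composition * .AVG_MASS[names(composition)])
}

.checkComposition <- function(composition) {
  if (is.null(names(composition)))
    stop("composition must be a named count vector")
  unknown <- setdiff(names(composition), .ELEMENTS)
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  if (any(composition < 0) || any(composition != round(composition)))
    stop("element counts must be nonnegative integers")
  composition[composition > 0]
}

## Convolve two (probability, mean-mass) distributions indexed by
## neutron offset 0,1,2,...; exact for abundances, and mass-tracking is
## the abundance-weighted mean within each offset (centroid-exact).
.convolveDist <- function(a, b, tol = 1e-15) {
  na <- length(a$p); nb <- length(b$p)
  p <- numeric(na + nb - 1)
  m <- numeric(na + nb - 1)
  for (i in seq_len(na)) {
    if (a$p[i] < tol) next
    idx <- i:(i + nb - 1)
    w <- a$p[i] * b$p
    p[idx] <- p[idx] + w
    m[idx] <- m[idx] + w * (a$m[i] + b$m)
  }
  keep <- p > 0
  m[keep] <- m[keep] / p[keep]
  last <- max(which(p > tol * max(p)), 1)
  list(p = p[seq_len(last)], m = m[seq_len(last)])
}

## Distribution of n atoms of one element, by binary exponentiation.
.elementDist <- function(element, n) {
  iso <- .ISOTOPES[[element]]
  width <- max(iso$offset) + 1L
  base <- list(p = numeric(width), m = numeric(width))
  base$p[iso$offset + 1L] <- iso$abundance
  base$m[iso$offset + 1L] <- iso$mass
  out <- NULL
  sq <- base
  k <- n
  while (k > 0) {
    if (k %% 2 == 1)
      out <- if (is.null(out)) sq else .convolveDist(out, sq)
    k <- k %/% 2
    if (k > 0) sq <- .convolveDist(sq, sq)
  }
  out
}

#' Natural isotope envelope of an elemental composition
#'
#' Builds the isotopologue distribution by iterated convolution of the
#' per-element isotope tables. Isotopologues are aggregated by neutron
#' count, each aggregate carrying the abundance-weighted mean mass, so
#' centroids are exact. Peaks below `truncation` of the maximum are
#' dropped and the envelope renormalized.
#'
#' @param composition named integer vector of element counts (C,H,N,O,S).
#' @param truncation abundance threshold relative to the tallest peak,
#'   in (0, 1).
#' @return a normalized [IsotopeEnvelope-class]. An empty composition
#'   yields the degenerate single peak at mass 0 (flagged
#'   `"degenerate"`).
#' @examples
#' naturalEnvelope(c(C = 1))               # 12C / 13C doublet
#' naturalEnvelope(compositionFromSequence("PEPTIDE"))
#' @export
naturalEnvelope <- function(composition, truncation = 1e-5) {
  if (!is.numeric(truncation) || truncation <= 0 || truncation >= 1)
    stop("truncation must lie strictly between 0 and 1")
  comp <- tryCatch(.checkComposition(composition),
                   error = function(e) stop(e))
  if (!length(comp))
    return(IsotopeEnvelope(0, 1, normalized = TRUE, flags = "degenerate"))
  dist <- NULL
  for (el in names(comp)) {
    d <- .elementDist(el, comp[[el]])
    dist <- if (is.null(dist)) d else .convolveDist(dist, d)
  }
  keep <- dist$p >= truncation * max(dist$p)
  p <- dist$p[keep]
  IsotopeEnvelope(dist$m[keep], p / sum(p), normalized = TRUE)
}

#' Number of exchange-competent backbone amides
#'
#' Standard HDX counting: every residue contributes one backbone amide
#' except the N-terminal residue (fast back-exchange) and prolines
#' (no amide hydrogen).
#'
#' @param sequence nonempty amino-acid string.
#' @return integer count.
#' @examples
#' nExchangeableAmides("AGPM")  # 2
#' @export
nExchangeableAmides <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence) ||
      !nzchar(sequence))
    stop("sequence must be a nonempty string")
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!aa %in% rownames(.RESIDUE_COMPOSITION))
  if (length(bad))
    stop(sprintf("unknown amino-acid letter '%s' at position %d",
                 aa[bad[1]], bad[1]))
  n <- length(aa)
  as.integer(n - 1L - sum(aa[-1] == "P"))
}

## Coalesce sticks closer than `tol` Da into abundance-weighted means.
## Preserves total abundance and the overall centroid exactly.
.mergePeaks <- function(mass, abundance, tol = 0.5) {
  o <- order(mass)
  mass <- mass[o]; abundance <- abundance[o]
  grp <- cumsum(c(1, diff(mass) >= tol))
  p <- as.numeric(tapply(abundance, grp, sum))
  m <- as.numeric(tapply(mass * abundance, grp, sum)) / p
  list(mass = m, abundance = p)
}

#' Normalize an envelope to unit total abundance
#'
#' @param env an [IsotopeEnvelope-class].
#' @return the envelope with abundances summing to 1.
#' @export
normalizeEnvelope <- function(env) {
  stopifnot(is(env, "IsotopeEnvelope"))
  s <- sum(env@abundance)
  if (s <= 0) stop("cannot normalize an all-zero envelope")
  IsotopeEnvelope(env@mass, env@abundance / s, normalized = TRUE,
                  flags = env@flags)
}

#' Convolve an envelope with binomial deuterium incorporation
#'
#' Models pulse labeling of `nAmides` equivalent backbone amides, each
#' incorporating deuterium with probability `pIncorp` (capped by the
#' D2O fraction of the labeling buffer). The envelope is convolved with
#' Binomial(nAmides, pIncorp) placed at multiples of the H->D mass
#' difference (1.00628 Da); the centroid shifts by exactly
#' `nAmides * pIncorp * 1.00628` Da.
#'
#' @param env an [IsotopeEnvelope-class].
#' @param nAmides nonnegative integer number of exchanging amides.
#' @param pIncorp incorporation probability in [0, 1].
#' @return a normalized [IsotopeEnvelope-class].
#' @examples
#' env <- naturalEnvelope(c(C = 10, H = 20, N = 4, O = 5))
#' shifted <- applyDeuteration(env, 8, 0.7)
#' centroidMass(shifted) - centroidMass(env)  # 8 * 0.7 * 1.00628
#' @export
applyDeuteration <- function(env, nAmides, pIncorp) {
  stopifnot(is(env, "IsotopeEnvelope"))
  if (!is.numeric(pIncorp) || length(pIncorp) != 1 || is.na(pIncorp) ||
      pIncorp < 0 || pIncorp > 1)
    stop("pIncorp must lie in [0, 1]")
  if (!is.numeric(nAmides) || nAmides < 0 || nAmides != round(nAmides))
    stop("nAmides must be a nonnegative integer")
  nAmides <- as.integer(nAmides)
  if (nAmides == 0L || pIncorp == 0)
    return(normalizeEnvelope(env))
  w <- stats::dbinom(0:nAmides, nAmides, pIncorp)
  keep <- w > 1e-12
  j <- (0:nAmides)[keep]; w <- w[keep]
  mass <- outer(env@mass, j * HD_MASS_DIFF, "+")
  ab <- outer(env@abundance, w)
  merged <- .mergePeaks(as.vector(mass), as.vector(ab))
  IsotopeEnvelope(merged$mass, merged$abundance / sum(merged$abundance),
                  normalized = TRUE, flags = env@flags)
}

#' Mix folded and unfolded envelopes
#'
#' Pointwise-weighted mixture `(1 - w) * folded + w * unfolded`,
#' coalescing coincident sticks. The mixture centroid is the same
#' weighted mean of the component centroids.
#'
#' @param folded,unfolded normalized [IsotopeEnvelope-class] objects.
#' @param wUnfolded mixture weight of the unfolded state, in [0, 1].
#' @return a normalized [IsotopeEnvelope-class].
#' @export
mixEnvelopes <- function(folded, unfolded, wUnfolded) {
  stopifnot(is(folded, "IsotopeEnvelope"), is(unfolded, "IsotopeEnvelope"))
  if (!folded@normalized || !unfolded@normalized)
    stop("both envelopes must be normalized before mixing")
  if (!is.numeric(wUnfolded) || length(wUnfolded) != 1 || is.na(wUnfolded) ||
      wUnfolded < 0 || wUnfolded > 1)
    stop("wUnfolded must lie in [0, 1]")
  if (wUnfolded == 0) return(folded)
  if (wUnfolded == 1) return(unfolded)
  merged <- .mergePeaks(c(folded@mass, unfolded@mass),
                        c((1 - wUnfolded) * folded@abundance,
                          wUnfolded * unfolded@abundance))
  IsotopeEnvelope(merged$mass, merged$abundance / sum(merged$abundance),
                  normalized = TRUE)
}

#' Convert an envelope to m/z coordinates
#'
#' `m/z = (mass + charge * 1.00728) / charge`. The inverse, [fromMz()],
#' recovers neutral masses to better than 1e-6 Da.
#'
#' @param env an [IsotopeEnvelope-class].
#' @param charge positive integer charge state.
#' @return data.frame with columns `mz` and `abundance`.
#' @export
toMz <- function(env, charge) {
  stopifnot(is(env, "IsotopeEnvelope"))
  if (!is.numeric(charge) || length(charge) != 1 || is.na(charge) ||
      charge < 1 || charge != round(charge))
    stop("charge must be a positive integer")
  data.frame(mz = (env@mass + charge * PROTON_MASS) / charge,
             abundance = env@abundance)
}

#' Convert m/z sticks back to a neutral-mass envelope
#'
#' @param mzPeaks data.frame with columns `mz` and `abundance`.
#' @param charge positive integer charge state.
#' @param normalized logical, whether the abundances sum to 1.
#' @return an [IsotopeEnvelope-class].
#' @export
fromMz <- function(mzPeaks, charge, normalized = FALSE) {
  if (!is.numeric(charge) || length(charge) != 1 || is.na(charge) ||
      charge < 1 || charge != round(charge))
    stop("charge must be a positive integer")
  if (!all(c("mz", "abundance") %in% names(mzPeaks)))
    stop("mzPeaks must have columns mz and abundance")
  IsotopeEnvelope(mzPeaks$mz * charge - charge * PROTON_MASS,
                  mzPeaks$abundance, normalized = normalized)
}

#' Write an envelope as two-column delimited text
#'
#' The serialization is a comma-delimited table with the mandatory
#' header `mass_da,abundance`.
#'
#' @param env an [IsotopeEnvelope-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEnvelope <- function(env, path) {
  stopifnot(is(env, "IsotopeEnvelope"))
  utils::write.csv(data.frame(mass_da = env@mass, abundance = env@abundance),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an envelope written by [writeEnvelope()]
#'
#' @param path input file path.
#' @param normalized logical, whether the stored abundances sum to 1.
#' @return an [IsotopeEnvelope-class].
#' @export
readEnvelope <- function(path, normalized = FALSE) {
  df <- utils::read.csv(path)
  if (!all(c("mass_da", "abundance") %in% names(df)))
    stop("envelope file must have header columns mass_da, abundance")
  IsotopeEnvelope(df$mass_da, df$abundance, normalized = normalized)
}
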