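## Continuous-labeling uptake analytics: relative uptake, residue heat
## maps, butterfly differences with the max-replicate-SD significance
## rule, EX1/EX2 width diagnostics and sequence coverage.

#' Relative deuterium uptake
#'
#' Uptake divided by the uptake of the fully exchanged control of the
#' same peptide. Values may marginally exceed 1 under noise; they are
#' flagged (attribute `exceeds_control`), not clipped.
#'
#' @param uptake uptake in Da.
#' @param controlUptake full-deuteration control uptake in Da (> 0).
#' @return numeric ratio(s), with attribute `exceeds_control` when any
#'   ratio exceeds 1.
#' @export
relativeUptake <- function(uptake, controlUptake) {
  if (any(!is.finite(controlUptake)) || any(controlUptake <= 0))
    stop("controlUptake must be positive")
  r <- uptake / controlUptake
  if (any(r > 1, na.rm = TRUE)) attr(r, "exceeds_control") <- TRUE
  r
}

#' Uptake table from continuous-labeling spectra
#'
#' Computes per-replicate centroid uptake relative to each peptide's
#' undeuterated envelope, aggregates replicates to mean +/- SD, and
#' adds the relative uptake against the full-deuteration control
#' (`nExchangeable * d2oFraction * 1.00628` Da, the asymptotic uptake
#' of a fully exchanged peptide under the labeling buffer).
#'
#' @param spectra list of [SyntheticSpectrum-class] objects from
#'   [simulateContinuousLabeling()].
#' @return data.frame with columns `peptide`, `start`, `end`, `time_s`,
#'   `uptake_da`, `rel_uptake`, `sd`, `n`.
#' @export
uptakeTable <- function(spectra) {
  if (!length(spectra)) stop("no spectra supplied")
  recs <- do.call(rbind, lapply(spectra, function(sp) {
    pep <- sp@peptide
    nat <- naturalEnvelope(peptideComposition(pep))
    ref <- centroidMass(nat)
    d2o <- sp@metadata$d2oFraction
    if (is.null(d2o)) d2o <- 0.70
    control <- peptideExchangeable(pep) * d2o * HD_MASS_DIFF
    data.frame(peptide = sprintf("%s_%d_%d", pep@protein, pep@start,
                                 pep@end),
               start = pep@start, end = pep@end,
               time_s = sp@metadata$time_s,
               uptake = envelopeUptake(sp@envelope, ref),
               control = control)
  }))
  agg <- do.call(rbind, lapply(
    split(recs, list(recs$peptide, recs$time_s), drop = TRUE),
    function(g) {
      data.frame(peptide = g$peptide[1], start = g$start[1],
                 end = g$end[1], time_s = g$time_s[1],
                 uptake_da = mean(g$uptake),
                 rel_uptake = mean(g$uptake) / g$control[1],
                 sd = if (nrow(g) > 1) stats::sd(g$uptake) else NA_real_,
                 n = nrow(g))
    }))
  rownames(agg) <- NULL
  agg[order(agg$start, agg$end, agg$time_s), ]
}

#' Residue-level relative-uptake heat map matrix
#'
#' Projects per-peptide relative uptake onto the primary sequence: the
#' value of each residue at each time is the unweighted mean of all
#' covering peptides (shortest-peptide priority available as an
#' option). Residues covered by no peptide are `NA` (missing), never 0.
#'
#' @param records uptake data.frame as from [uptakeTable()] (columns
#'   `peptide`, `start`, `end`, `time_s`, `rel_uptake`).
#' @param proteinLength protein length in residues.
#' @param rule `"mean"` (default) or `"shortest"` (value of the
#'   shortest covering peptide).
#' @return numeric matrix residues x times with `NA` for uncovered
#'   residues; attribute `provenance` lists the covering peptides per
#'   residue.
#' @export
heatmapMatrix <- function(records, proteinLength,
                          rule = c("mean", "shortest")) {
  rule <- match.arg(rule)
  if (any(records$start < 1 | records$end > proteinLength))
    stop("peptide coordinates outside [1, proteinLength]")
  times <- sort(unique(records$time_s))
  mat <- matrix(NA_real_, nrow = proteinLength, ncol = length(times),
                dimnames = list(seq_len(proteinLength), times))
  provenance <- vector("list", proteinLength)
  for (j in seq_along(times)) {
    sub <- records[records$time_s == times[j], ]
    for (res in seq_len(proteinLength)) {
      cov <- sub[sub$start <= res & sub$end >= res, ]
      if (!nrow(cov)) next
      mat[res, j] <- if (rule == "mean") mean(cov$rel_uptake)
        else cov$rel_uptake[which.min(cov$end - cov$start)]
      if (j == 1) provenance[[res]] <- unique(cov$peptide)
    }
  }
  if (nrow(records)) {
    for (res in seq_len(proteinLength)) {
      cov <- records[records$start <= res & records$end >= res, ]
      provenance[[res]] <- unique(cov$peptide)
    }
  }
  attr(mat, "provenance") <- provenance
  mat
}

#' Significance threshold from replicate standard deviations
#'
#' The largest replicate SD across all peptides and data sets, applied
#' symmetrically about zero in butterfly difference plots.
#'
#' @param sds numeric vector of replicate SDs (Da); `NA`s are dropped.
#' @return the maximum SD.
#' @export
significanceThreshold <- function(sds) {
  sds <- sds[!is.na(sds)]
  if (!length(sds)) stop("at least one SD value is required")
  max(sds)
}

#' Butterfly differences between two uptake data sets
#'
#' Per-peptide, per-time uptake difference (variant minus reference) on
#' the intersection of the two peptide sets; mismatched peptides are
#' reported in the `dropped` attribute. When a `bin` column is present
#' in both inputs (e.g. bimodality bins such as 10-15 or 15-20 percent
#' bimodality), the join includes it, so differencing happens within
#' bins. Differences larger in magnitude than the max-replicate-SD
#' threshold are flagged significant.
#'
#' @param reference,variant uptake data.frames as from [uptakeTable()].
#' @param threshold significance threshold in Da; defaults to
#'   [significanceThreshold()] over the SDs of both inputs.
#' @return data.frame with columns `peptide`, `start`, `end`, `time_s`,
#'   (`bin`,) `diff_da`, `significant`; attributes `threshold` and
#'   `dropped`.
#' @export
butterflyDifferences <- function(reference, variant, threshold = NULL) {
  keys <- c("peptide", "start", "end", "time_s")
  if ("bin" %in% names(reference) && "bin" %in% names(variant))
    keys <- c(keys, "bin")
  m <- merge(reference, variant, by = keys,
             suffixes = c("_ref", "_var"))
  if (!nrow(m)) stop("no peptides shared between reference and variant")
  dropped <- union(
    setdiff(reference$peptide, variant$peptide),
    setdiff(variant$peptide, reference$peptide))
  if (is.null(threshold))
    threshold <- significanceThreshold(c(m$sd_ref, m$sd_var))
  out <- m[keys]
  out$diff_da <- m$uptake_da_var - m$uptake_da_ref
  out$significant <- abs(out$diff_da) > threshold
  out <- out[order(out$start, out$end, out$time_s), ]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "dropped") <- dropped
  out
}

#' Envelope-width metric for EX1/EX2 classification
#'
#' The second central moment (variance about the centroid, Da^2) of
#' each envelope in a labeling time series. Cooperative (EX1) opening
#' transiently broadens the envelope: for a two-mode mixture with
#' component variance sigma^2, separation d and open fraction w the
#' variance is `sigma^2 + w(1-w) d^2`, maximal at w = 0.5. A series is
#' classified `"EX1-containing"` when the maximum variance exceeds the
#' earliest-time variance by `factor` (default 2), otherwise `"EX2"`.
#'
#' @param envelopes list of [IsotopeEnvelope-class] (or
#'   [SyntheticSpectrum-class]) objects for one peptide over time.
#' @param times numeric labeling times (seconds) matching `envelopes`.
#' @param factor variance-increase factor required for the EX1 call.
#' @return list with `table` (data.frame time_s, variance) and
#'   `classification` (`"EX1-containing"`, `"EX2"`, or `NA` when only
#'   one time point is available).
#' @export
ex1WidthMetric <- function(envelopes, times, factor = 2) {
  if (length(envelopes) != length(times))
    stop("envelopes and times must have equal length")
  variance <- vapply(envelopes, function(e) {
    if (is(e, "SyntheticSpectrum")) e <- e@envelope
    mu <- centroidMass(e)
    sum(e@abundance * (e@mass - mu)^2) / sum(e@abundance)
  }, numeric(1))
  o <- order(times)
  tab <- data.frame(time_s = times[o], variance = variance[o])
  cls <- if (nrow(tab) < 2) NA_character_
    else if (max(tab$variance) >= factor * tab$variance[1])
      "EX1-containing" else "EX2"
  list(table = tab, classification = cls)
}

#' Sequence coverage of a peptide map
#'
#' Percentage of residues covered by the union of the peptides.
#' Overlaps and duplicates are allowed; out-of-range peptides are
#' rejected.
#'
#' @param peptides list of [PeptideSpec-class] objects.
#' @param proteinLength protein length in residues.
#' @return coverage percentage in [0, 100].
#' @examples
#' peps <- list(PeptideSpec("P", 1, 10), PeptideSpec("P", 5, 20))
#' sequenceCoverage(peps, 40)  # 50
#' @export
sequenceCoverage <- function(peptides, proteinLength) {
  if (!length(peptides)) return(0)
  covered <- logical(proteinLength)
  for (p in peptides) {
    stopifnot(is(p, "PeptideSpec"))
    if (p@start < 1 || p@end > proteinLength)
      stop(sprintf("peptide %d-%d outside [1, %d]", p@start, p@end,
                   proteinLength))
    covered[p@start:p@end] <- TRUE
  }
  100 * sum(covered) / proteinLength
}
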