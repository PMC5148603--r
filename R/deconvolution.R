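## Two-Gaussian deconvolution of (possibly bimodal) isotope envelopes
## with BIC model selection; the fraction unfolded is the area ratio of
## the two fitted components.

.gaussArea <- function(amplitude, sigma) amplitude * sigma * sqrt(2 * pi)

.bic <- function(rss, n, k) n * log(rss / n) + k * log(n)

.componentFrame <- function(centroid, sigma, amplitude) {
  data.frame(centroid = centroid, sigma = sigma, amplitude = amplitude,
             area = .gaussArea(amplitude, sigma))
}

#' Fit a single Gaussian to a stick envelope
#'
#' The null model for bimodality detection: one Gaussian least-squares
#' fit of the stick intensities against mass. Sticks are treated as
#' weighted points on a continuous mass axis (no profile re-binning).
#'
#' @param env an [IsotopeEnvelope-class] (raw or normalized) with at
#'   least 4 nonzero peaks.
#' @param sigmaBounds lower/upper bounds on the width (Da).
#' @return a [BimodalFit-class] with `model = "unimodal"`; the unfolded
#'   fraction is left `NA` (assignment happens in [selectModel()]).
#' @export
fitUnimodal <- function(env, sigmaBounds = c(0.3, 50)) {
  stopifnot(is(env, "IsotopeEnvelope"))
  x <- env@mass; y <- env@abundance
  if (sum(y > 0) < 4)
    stop("need at least 4 peaks above baseline for a unimodal fit")
  mu0 <- sum(x * y) / sum(y)
  s0 <- sqrt(max(sum(y * (x - mu0)^2) / sum(y), 1e-12))
  flags <- character()
  if (s0 < sigmaBounds[1]) {
    ## degenerate envelope: essentially all mass at one stick
    flags <- c(flags, "degenerate", "width_pinned")
    s0 <- sigmaBounds[1]
  }
  s0 <- min(max(s0, sigmaBounds[1]), sigmaBounds[2])
  start <- list(A = max(y), mu = mu0, s = s0)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * s^2)),
                      data = data.frame(x = x, y = y), start = start,
                      lower = c(A = 0, mu = min(x), s = sigmaBounds[1]),
                      upper = c(A = Inf, mu = max(x), s = sigmaBounds[2]),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    cmp <- .componentFrame(mu0, s0, max(y))
    rss <- sum((y - cmp$amplitude *
                  exp(-(x - mu0)^2 / (2 * s0^2)))^2)
    return(new("BimodalFit", model = "unimodal", components = cmp,
               unfoldedFraction = NA_real_, residual = rss,
               bic = c(unimodal = .bic(rss, length(y), 3),
                       bimodal = NA_real_),
               converged = FALSE, ambiguous = FALSE,
               flags = c(flags, "nls_failure")))
  }
  cf <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  if (abs(cf["s"] - sigmaBounds[1]) < 1e-8)
    flags <- unique(c(flags, "width_pinned"))
  new("BimodalFit", model = "unimodal",
      components = .componentFrame(cf[["mu"]], cf[["s"]], cf[["A"]]),
      unfoldedFraction = NA_real_, residual = rss,
      bic = c(unimodal = .bic(rss, length(y), 3), bimodal = NA_real_),
      converged = isTRUE(fit$convInfo$isConv), ambiguous = FALSE,
      flags = flags)
}

#' Fit two Gaussians anchored at folded/unfolded reference centroids
#'
#' Constrained least squares: each centroid may move at most
#' `centroidWindow` Da from its reference, widths are bounded in
#' `sigmaBounds` and amplitudes are nonnegative. The unfolded fraction
#' is the area of the high-mass component over the total area; the
#' folded component is always the lower-centroid one.
#'
#' @param env an [IsotopeEnvelope-class].
#' @param foldedRef,unfoldedRef reference centroid masses (Da) of the
#'   folded and unfolded states (folded < unfolded; separation must
#'   exceed twice the initial width).
#' @param sigmaBounds global width bounds in Da (default 0.5 to 6).
#' @param centroidWindow allowed centroid excursion from each reference
#'   (default 3 Da).
#' @param initWidth initial width of both components (default 2 Da),
#'   used when no reference widths are given.
#' @param refWidths optional numeric vector of length 2: the widths of
#'   the pure folded and unfolded reference envelopes (see
#'   [referenceStates()]). When supplied, each component's width is
#'   constrained to `widthWindow` times its reference width
#'   (intersected with `sigmaBounds`), which stops the minor component
#'   from ballooning to absorb the skewed tail of the major one.
#' @param widthWindow multiplicative width window around each reference
#'   width (default 0.8 to 1.2).
#' @return a [BimodalFit-class] with `model = "bimodal"`. On
#'   non-convergence the fraction is `NA` and the fit flagged - never
#'   silently 0.
#' @export
fitBimodal <- function(env, foldedRef, unfoldedRef,
                       sigmaBounds = c(0.5, 6), centroidWindow = 3,
                       initWidth = 2, refWidths = NULL,
                       widthWindow = c(0.8, 1.2)) {
  stopifnot(is(env, "IsotopeEnvelope"))
  if (!is.finite(foldedRef) || !is.finite(unfoldedRef))
    stop("folded and unfolded reference centroids are required")
  if (foldedRef >= unfoldedRef)
    stop("folded reference centroid must be below the unfolded one")
  if ((unfoldedRef - foldedRef) <= 2 * initWidth)
    stop("reference separation must exceed twice the initial width")
  x <- env@mass; y <- env@abundance
  if (sum(y > 0) < 4)
    stop("need at least 4 peaks above baseline for a bimodal fit")
  nearMax <- function(ref) {
    sel <- abs(x - ref) <= max(centroidWindow, 2 * initWidth)
    if (any(sel)) max(y[sel]) else 0
  }
  eps <- 1e-6 * max(y)
  if (!is.null(refWidths)) {
    s1b <- c(max(sigmaBounds[1], refWidths[1] * widthWindow[1]),
             min(sigmaBounds[2], refWidths[1] * widthWindow[2]))
    s2b <- c(max(sigmaBounds[1], refWidths[2] * widthWindow[1]),
             min(sigmaBounds[2], refWidths[2] * widthWindow[2]))
    s10 <- min(max(refWidths[1], s1b[1]), s1b[2])
    s20 <- min(max(refWidths[2], s2b[1]), s2b[2])
  } else {
    s1b <- s2b <- sigmaBounds
    s10 <- s20 <- min(max(initWidth, sigmaBounds[1]), sigmaBounds[2])
  }
  start <- list(A1 = max(nearMax(foldedRef), eps), m1 = foldedRef,
                s1 = s10,
                A2 = max(nearMax(unfoldedRef), eps), m2 = unfoldedRef,
                s2 = s20)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A1 * exp(-(x - m1)^2 / (2 * s1^2)) +
          A2 * exp(-(x - m2)^2 / (2 * s2^2)),
      data = data.frame(x = x, y = y), start = start,
      lower = c(A1 = 0, m1 = foldedRef - centroidWindow,
                s1 = s1b[1], A2 = 0,
                m2 = unfoldedRef - centroidWindow, s2 = s2b[1]),
      upper = c(A1 = Inf, m1 = foldedRef + centroidWindow,
                s1 = s1b[2], A2 = Inf,
                m2 = unfoldedRef + centroidWindow, s2 = s2b[2]),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !isTRUE(fit$convInfo$isConv)) {
    cmp <- .componentFrame(c(foldedRef, unfoldedRef),
                           rep(initWidth, 2),
                           c(start$A1, start$A2))
    return(new("BimodalFit", model = "bimodal", components = cmp,
               unfoldedFraction = NA_real_, residual = NA_real_,
               bic = c(unimodal = NA_real_, bimodal = NA_real_),
               converged = FALSE, ambiguous = FALSE,
               flags = "nls_failure"))
  }
  cf <- stats::coef(fit)
  ## ordering invariant: folded component = lower centroid
  ord <- order(c(cf[["m1"]], cf[["m2"]]))
  centroids <- c(cf[["m1"]], cf[["m2"]])[ord]
  sigmas <- c(cf[["s1"]], cf[["s2"]])[ord]
  amps <- c(cf[["A1"]], cf[["A2"]])[ord]
  cmp <- .componentFrame(centroids, sigmas, amps)
  rss <- sum(stats::resid(fit)^2)
  total <- sum(cmp$area)
  frac <- if (total > 0) cmp$area[2] / total else NA_real_
  flags <- if (total > 0) character() else "zero_area"
  new("BimodalFit", model = "bimodal", components = cmp,
      unfoldedFraction = frac, residual = rss,
      bic = c(unimodal = NA_real_, bimodal = .bic(rss, length(y), 6)),
      converged = TRUE, ambiguous = FALSE, flags = flags)
}

#' Deconvolute an envelope with unimodal/bimodal model selection
#'
#' Fits both the single-Gaussian null model and the constrained
#' two-Gaussian model and accepts bimodality when
#' `BIC(unimodal) - BIC(bimodal) >= deltaBicThreshold` (default 6, the
#' conventional "strong evidence" cutoff). When the unimodal model is
#' retained the fraction is assigned 0 if its centroid lies within 20
#' percent of the folded-to-unfolded span from the folded reference, 1
#' if within 20 percent of the unfolded reference, and `NA` with an
#' ambiguity flag otherwise.
#'
#' @inheritParams fitBimodal
#' @param deltaBicThreshold BIC difference required to accept the
#'   bimodal model (default 6).
#' @param assignWindow fraction of the folded-to-unfolded span used for
#'   the unimodal 0/1 assignment (default 0.2).
#' @return a [BimodalFit-class] carrying both model BICs.
#' @export
selectModel <- function(env, foldedRef, unfoldedRef,
                        deltaBicThreshold = 6, assignWindow = 0.2,
                        sigmaBounds = c(0.5, 6), centroidWindow = 3,
                        initWidth = 2, refWidths = NULL,
                        widthWindow = c(0.8, 1.2)) {
  uni <- fitUnimodal(env)
  bi <- tryCatch(
    fitBimodal(env, foldedRef, unfoldedRef, sigmaBounds = sigmaBounds,
               centroidWindow = centroidWindow, initWidth = initWidth,
               refWidths = refWidths, widthWindow = widthWindow),
    error = function(e) NULL)
  bicU <- uni@bic[["unimodal"]]
  bicB <- if (!is.null(bi) && bi@converged) bi@bic[["bimodal"]]
          else NA_real_
  if (!is.na(bicU) && !is.na(bicB) &&
      (bicU - bicB) >= deltaBicThreshold) {
    bi@bic <- c(unimodal = bicU, bimodal = bicB)
    return(bi)
  }
  ## unimodal retained: assign 0/1 by proximity to the references
  span <- unfoldedRef - foldedRef
  mu <- uni@components$centroid[1]
  flags <- uni@flags
  ambiguous <- FALSE
  frac <- if (!uni@converged) NA_real_
    else if (abs(mu - foldedRef) <= assignWindow * span) 0
    else if (abs(mu - unfoldedRef) <= assignWindow * span) 1
    else { ambiguous <- TRUE; NA_real_ }
  if (ambiguous) flags <- c(flags, "ambiguous_unimodal")
  new("BimodalFit", model = "unimodal", components = uni@components,
      unfoldedFraction = frac, residual = uni@residual,
      bic = c(unimodal = bicU, bimodal = bicB),
      converged = uni@converged, ambiguous = ambiguous, flags = flags)
}

#' Average-mass deuterium uptake of an envelope
#'
#' The centroid mass of the (possibly bimodal) envelope minus the
#' undeuterated reference centroid. Computable without deconvolution.
#'
#' @param env an [IsotopeEnvelope-class].
#' @param referenceCentroid centroid mass (Da) of the undeuterated
#'   envelope.
#' @return uptake in Da.
#' @export
envelopeUptake <- function(env, referenceCentroid) {
  if (missing(referenceCentroid) || !is.finite(referenceCentroid))
    stop("an undeuterated reference centroid is required")
  centroidMass(env) - referenceCentroid
}

#' Deconvolute a batch of simulated spectra
#'
#' Runs [selectModel()] on every spectrum. Reference centroids (and the
#' width windows anchored on the pure-state envelope widths) default to
#' the noiseless folded/unfolded states derived from each spectrum's
#' peptide and labeling metadata.
#'
#' @param spectra list of [SyntheticSpectrum-class] objects.
#' @param foldedRef,unfoldedRef optional explicit reference centroids.
#' @param deltaBicThreshold passed to [selectModel()].
#' @return data.frame with one row per spectrum: preset, replicate,
#'   time_min, model, fraction_unfolded, centroid_folded,
#'   centroid_unfolded, residual, converged, ambiguous, flags, plus
#'   condition metadata (inhibitor, inhibitor_conc, substrate_conc,
#'   protectant, true_fraction).
#' @export
deconvolveSpectra <- function(spectra, foldedRef = NULL,
                              unfoldedRef = NULL,
                              deltaBicThreshold = 6) {
  if (!length(spectra)) stop("no spectra to deconvolute")
  autoRefs <- is.null(foldedRef) || is.null(unfoldedRef)
  refCache <- list()
  rows <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    if (autoRefs) {
      key <- sprintf("%s_%s_%s", sp@peptide@protein, sp@peptide@start,
                     sp@peptide@end)
      if (is.null(refCache[[key]])) {
        md <- sp@metadata
        pf <- if (!is.null(md$pFolded)) md$pFolded else 0.25
        d2o <- if (!is.null(md$d2oFraction)) md$d2oFraction else 0.70
        refCache[[key]] <- referenceStates(
          sp@peptide, labelingCondition(d2oFraction = d2o), pFolded = pf)
      }
      st <- refCache[[key]]
      refs <- c(folded = st$centroid[1], unfolded = st$centroid[2])
      refWidths <- st$width
    } else {
      refs <- c(folded = foldedRef, unfolded = unfoldedRef)
      refWidths <- NULL
    }
    fit <- selectModel(sp@envelope, refs[["folded"]], refs[["unfolded"]],
                       deltaBicThreshold = deltaBicThreshold,
                       refWidths = refWidths)
    cmp <- fit@components
    md <- sp@metadata
    rows[[i]] <- data.frame(
      preset = sp@preset, replicate = sp@replicate,
      time_min = sp@timeMin, model = fit@model,
      fraction_unfolded = fit@unfoldedFraction,
      centroid_folded = cmp$centroid[1],
      centroid_unfolded = if (nrow(cmp) == 2) cmp$centroid[2]
                          else NA_real_,
      residual = fit@residual, converged = fit@converged,
      ambiguous = fit@ambiguous,
      flags = paste(fit@flags, collapse = ";"),
      inhibitor = if (!is.null(md$inhibitor)) md$inhibitor
                  else NA_character_,
      inhibitor_conc = if (!is.null(md$inhibitorConc))
                         md$inhibitorConc else NA_real_,
      substrate_conc = if (!is.null(md$substrateConc))
                         md$substrateConc else NA_real_,
      protectant = if (!is.null(md$protectant)) md$protectant
                   else NA_character_,
      true_fraction = if (!is.null(md$trueFraction)) md$trueFraction
                      else NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
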