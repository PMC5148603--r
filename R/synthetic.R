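## Seeded synthetic-data generator: replicate noisy pulse-label and
## continuous-labeling spectra under the study's experimental conditions.

#' Labeling condition parameters
#'
#' @param d2oFraction volume fraction of D2O in the labeling buffer
#'   (default 0.70, the 70 percent (v/v) exchange buffer).
#' @param pulseDuration pulse length in seconds (default 10).
#' @param temperature incubation temperature in degrees C (metadata).
#' @param continuousTimes labeling times in seconds for
#'   continuous-labeling experiments (default 10, 100, 1000).
#' @return a validated list of class `LabelingCondition`.
#' @export
labelingCondition <- function(d2oFraction = 0.70, pulseDuration = 10,
                              temperature = 25,
                              continuousTimes = c(10, 100, 1000)) {
  if (d2oFraction <= 0 || d2oFraction > 1)
    stop("d2oFraction must lie in (0, 1]")
  if (pulseDuration <= 0) stop("pulseDuration must be positive")
  structure(list(d2oFraction = d2oFraction, pulseDuration = pulseDuration,
                 temperature = temperature,
                 continuousTimes = sort(continuousTimes)),
            class = "LabelingCondition")
}

#' Noise model for synthetic spectra
#'
#' Per-peak multiplicative Gaussian noise (coefficient of variation
#' `cv`) plus additive baseline noise scaled to the tallest peak;
#' negative intensities are clipped to zero. A seed is mandatory for
#' every stochastic call.
#'
#' @param cv multiplicative coefficient of variation per peak
#'   (default 0.03).
#' @param baseline additive noise SD as a fraction of the maximum peak
#'   (default 0.005).
#' @param seed integer RNG seed (mandatory).
#' @return a validated list of class `NoiseModel`.
#' @export
noiseModel <- function(cv = 0.03, baseline = 0.005, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a seed is mandatory for any stochastic call")
  if (cv < 0 || baseline < 0) stop("cv and baseline must be nonnegative")
  structure(list(cv = cv, baseline = baseline, seed = as.integer(seed)),
            class = "NoiseModel")
}

#' Empirical preset: a named condition with a known generating fraction
#'
#' @param name preset name.
#' @param fraction true unfolded fraction in [0, 1].
#' @param timeMin incubation time in minutes.
#' @param condition free-text condition description.
#' @param metadata named list of additional condition metadata.
#' @return a list of class `EmpiricalPreset`.
#' @export
empiricalPreset <- function(name, fraction, timeMin, condition = "",
                            metadata = list()) {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  structure(list(name = name, fraction = fraction, timeMin = timeMin,
                 condition = condition, metadata = metadata),
            class = "EmpiricalPreset")
}

#' Kinetic preset: rate parameters of the two-state unfolding model
#'
#' @param name preset name.
#' @param kSpont spontaneous unfolding rate, per minute.
#' @param efficacy catalytic unfolding efficacy: substrate molecules
#'   unfolded per inhibitor molecule per minute.
#' @param inhibitorConc inhibitor concentration in uM (may be `NA` in a
#'   template preset; supplied at simulation time).
#' @param substrateConc total substrate concentration in uM
#'   (default 10).
#' @param kDecay first-order decay rate of inhibitor activity, per
#'   minute (default 0).
#' @param inhibitor inhibitor identifier (metadata).
#' @return a list of class `KineticPreset`.
#' @export
kineticPreset <- function(name, kSpont, efficacy, inhibitorConc = NA_real_,
                          substrateConc = 10, kDecay = 0,
                          inhibitor = name) {
  if (kSpont < 0 || efficacy < 0 || kDecay < 0)
    stop("rates must be nonnegative")
  if (substrateConc <= 0) stop("substrateConc must be positive")
  if (!is.na(inhibitorConc) && inhibitorConc < 0)
    stop("inhibitorConc must be nonnegative")
  structure(list(name = name, kSpont = kSpont, efficacy = efficacy,
                 inhibitorConc = inhibitorConc,
                 substrateConc = substrateConc, kDecay = kDecay,
                 inhibitor = inhibitor),
            class = "KineticPreset")
}

#' Registry of study-condition presets
#'
#' Immutable named registry of the experimental conditions emulated by
#' the generator. Empirical presets carry the generating unfolded
#' fraction of a single incubation condition; kinetic presets carry the
#' rate parameters of the two-state model (the spontaneous rate is
#' calibrated so the spontaneous curve passes 29 percent at 30 min; the
#' spontaneous measurements themselves are not exactly first-order, so
#' fraction-level conditions are represented by empirical presets).
#'
#' @return named list with elements `empirical` and `kinetic`.
#' @examples
#' names(presetRegistry()$empirical)
#' getPreset("spont_30")$fraction
#' @export
presetRegistry <- function() {
  list(
    empirical = list(
      spont_5 = empiricalPreset("spont_5", 0.070, 5,
        "10 uM LPL alone, 25 C, 5 min"),
      spont_30 = empiricalPreset("spont_30", 0.29, 30,
        "10 uM LPL alone, 25 C, 30 min"),
      spont_30_dose = empiricalPreset("spont_30_dose", 0.286, 30,
        "10 uM LPL alone, 30 min (dose-response buffer control)"),
      wt1uM_5 = empiricalPreset("wt1uM_5", 0.603, 5,
        "10 uM LPL + 1 uM ANGPTL4 1-159, 5 min",
        list(inhibitor = "ANGPTL4_wt", inhibitorConc = 1.0)),
      wt0p25uM_30 = empiricalPreset("wt0p25uM_30", 0.74, 30,
        "10 uM LPL + 0.25 uM ANGPTL4 1-159, 30 min",
        list(inhibitor = "ANGPTL4_wt", inhibitorConc = 0.25)),
      wt2uM_10 = empiricalPreset("wt2uM_10", 0.87, 10,
        "10 uM LPL + 2 uM ANGPTL4 1-159, 10 min",
        list(inhibitor = "ANGPTL4_wt", inhibitorConc = 2.0)),
      wt2uM_10_gpihbp1 = empiricalPreset("wt2uM_10_gpihbp1", 0.08, 10,
        "as wt2uM_10 with 30 uM full-length GPIHBP1",
        list(inhibitor = "ANGPTL4_wt", inhibitorConc = 2.0,
             protectant = "GPIHBP1_1_131")),
      wt2uM_10_LU = empiricalPreset("wt2uM_10_LU", 0.79, 10,
        "as wt2uM_10 with 30 uM GPIHBP1 LU domain only",
        list(inhibitor = "ANGPTL4_wt", inhibitorConc = 2.0,
             protectant = "GPIHBP1_34_131")),
      wt2uM_10_acidic = empiricalPreset("wt2uM_10_acidic", 0.69, 10,
        "as wt2uM_10 with 30 uM GPIHBP1 acidic domain only",
        list(inhibitor = "ANGPTL4_wt", inhibitorConc = 2.0,
             protectant = "GPIHBP1_1_33"))
    ),
    kinetic = list(
      wt = kineticPreset("wt", kSpont = 0.0114, efficacy = 1.6,
                         kDecay = 0, inhibitor = "ANGPTL4_wt"),
      e15k = kineticPreset("e15k", kSpont = 0.0114, efficacy = 0.6,
                           kDecay = 0.05, inhibitor = "ANGPTL4_E15K")
    )
  )
}

#' Look up a preset by name
#'
#' @param name preset name (empirical or kinetic).
#' @return the preset object.
#' @export
getPreset <- function(name) {
  reg <- presetRegistry()
  all <- c(reg$empirical, reg$kinetic)
  if (!name %in% names(all))
    stop(sprintf("unknown preset '%s'; available presets: %s", name,
                 paste(names(all), collapse = ", ")))
  all[[name]]
}

#' Fraction unfolded under the two-state kinetic model
#'
#' `u(t) = 1 - exp(-(kSpont * t + kCatEff * g(t)))` with
#' `kCatEff = efficacy * inhibitorConc / substrateConc` and
#' `g(t) = t` for `kDecay = 0`, else
#' `(1 - exp(-kDecay * t)) / kDecay` (first-order decay of inhibitor
#' activity). `u(0) = 0` and `u` is monotone nondecreasing.
#'
#' @param t time(s) in minutes, nonnegative.
#' @param preset a [kineticPreset()] with `inhibitorConc` set (use 0 or
#'   `NA` efficacy-free presets for spontaneous-only curves).
#' @param inhibitorConc optional override of the preset concentration.
#' @return numeric vector of fractions in [0, 1).
#' @examples
#' p <- kineticPreset("spont", kSpont = 0.0114, efficacy = 0,
#'                    inhibitorConc = 0)
#' twoStateFraction(30, p)  # 0.290
#' @export
twoStateFraction <- function(t, preset, inhibitorConc = NULL) {
  if (!inherits(preset, "KineticPreset"))
    stop("preset must be a KineticPreset")
  if (any(t < 0)) stop("t must be nonnegative")
  conc <- if (!is.null(inhibitorConc)) inhibitorConc
          else preset$inhibitorConc
  if (is.na(conc)) conc <- 0
  kCat <- preset$efficacy * conc / preset$substrateConc
  g <- if (preset$kDecay == 0) t
       else (1 - exp(-preset$kDecay * t)) / preset$kDecay
  1 - exp(-(preset$kSpont * t + kCat * g))
}

## Apply the noise model to a normalized envelope; returns raw
## intensities scaled so the noiseless maximum would be 100.
.applyNoise <- function(env, noise, seed) {
  set.seed(seed)
  intensity <- env@abundance / max(env@abundance) * 100
  n <- length(intensity)
  intensity <- intensity * (1 + noise$cv * stats::rnorm(n)) +
    noise$baseline * 100 * stats::rnorm(n)
  IsotopeEnvelope(env@mass, pmax(intensity, 0), normalized = FALSE)
}

.makeSpectrum <- function(envNoisy, peptide, replicate, timeMin, preset,
                          metadata) {
  new("SyntheticSpectrum", envelope = envNoisy, peptide = peptide,
      replicate = as.integer(replicate), timeMin = timeMin,
      preset = preset, metadata = metadata)
}

#' Simulate replicate pulse-labeled spectra
#'
#' For every requested time and replicate, builds the folded-state
#' envelope (partial EX2 incorporation at `pFolded`), the unfolded-state
#' envelope (full incorporation at the D2O fraction), mixes them with
#' the generating unfolded fraction (the preset fraction for empirical
#' presets, [twoStateFraction()] for kinetic presets) and applies the
#' noise model. Identical seeds give bit-identical output; each
#' (preset, time, replicate) combination has its own derived RNG
#' stream.
#'
#' @param preset an [empiricalPreset()] or [kineticPreset()].
#' @param peptide a [PeptideSpec-class] (default the diagnostic
#'   hydrolase-domain peptide).
#' @param labeling a [labelingCondition()].
#' @param times time grid in minutes; defaults to the preset's own time
#'   for empirical presets (required for kinetic presets).
#' @param replicates number of replicate spectra per time (default 3,
#'   matching triplicate labeling).
#' @param noise a [noiseModel()] (its seed drives all randomness).
#' @param pFolded folded-state incorporation probability
#'   (default 0.25; must be below the D2O fraction so the folded and
#'   unfolded states are separable).
#' @param inhibitorConc optional concentration override for kinetic
#'   presets.
#' @return list of [SyntheticSpectrum-class] objects.
#' @export
simulatePulseSpectra <- function(preset, peptide = diagnosticPeptide(),
                                 labeling = labelingCondition(),
                                 times = NULL, replicates = 3,
                                 noise = noiseModel(seed = 1),
                                 pFolded = 0.25, inhibitorConc = NULL) {
  if (replicates < 1) stop("replicates must be >= 1")
  if (pFolded >= labeling$d2oFraction)
    stop("pFolded must be below the D2O fraction (states must be separable)")
  empirical <- inherits(preset, "EmpiricalPreset")
  if (!empirical && !inherits(preset, "KineticPreset"))
    stop("preset must be an EmpiricalPreset or KineticPreset")
  if (is.null(times))
    times <- if (empirical) preset$timeMin
             else stop("a time grid is required for kinetic presets")
  nat <- naturalEnvelope(peptideComposition(peptide))
  nex <- peptideExchangeable(peptide)
  foldedEnv <- applyDeuteration(nat, nex, pFolded)
  unfoldedEnv <- applyDeuteration(nat, nex, labeling$d2oFraction)
  conc <- if (!empirical) {
    if (!is.null(inhibitorConc)) inhibitorConc else preset$inhibitorConc
  } else if (!is.null(preset$metadata$inhibitorConc)) {
    preset$metadata$inhibitorConc
  } else NA_real_
  out <- vector("list", length(times) * replicates)
  k <- 0
  for (t in times) {
    w <- if (empirical) preset$fraction
         else twoStateFraction(t, preset, inhibitorConc = conc)
    mixture <- mixEnvelopes(foldedEnv, unfoldedEnv, w)
    for (r in seq_len(replicates)) {
      k <- k + 1
      seed <- .deriveSeed(noise$seed, preset$name, t * 1000, r)
      md <- list(trueFraction = w, pFolded = pFolded,
                 d2oFraction = labeling$d2oFraction, seed = seed,
                 inhibitorConc = conc,
                 substrateConc = if (!empirical) preset$substrateConc
                                 else 10,
                 inhibitor = if (!empirical) preset$inhibitor
                             else preset$metadata$inhibitor,
                 protectant = if (empirical) preset$metadata$protectant
                              else NULL)
      out[[k]] <- .makeSpectrum(.applyNoise(mixture, noise, seed),
                                peptide, r, t, preset$name, md)
    }
  }
  out
}

#' Simulate continuous-labeling spectra for protected regions
#'
#' Each region is described by a peptide, a protection factor `pf` and a
#' cooperative opening rate `kOpen` (per second). The closed-state
#' incorporation follows EX2 kinetics,
#' `pClosed(t) = d2o * (1 - exp(-kInt * t / pf))`, while a cooperatively
#' opened subpopulation `w(t) = 1 - exp(-kOpen * t)` is labeled at the
#' full D2O fraction (EX1 component). `kOpen = 0` gives pure EX2
#' (unimodal centroid drift); a very large `pf` with `kOpen > 0` gives
#' pure EX1 (two fixed modes with shifting weights).
#'
#' @param regionParams list of lists with elements `peptide`
#'   ([PeptideSpec-class]), `pf` (protection factor, >= 1) and `kOpen`
#'   (per second, >= 0).
#' @param labeling a [labelingCondition()]; its `continuousTimes` are
#'   the labeling times in seconds.
#' @param replicates replicates per region and time (default 3).
#' @param noise a [noiseModel()].
#' @param kInt intrinsic amide exchange rate in the unprotected state,
#'   per second (default 1).
#' @return list of [SyntheticSpectrum-class] objects; labeling time in
#'   seconds is kept in `metadata$time_s` (the `timeMin` slot holds
#'   minutes).
#' @export
simulateContinuousLabeling <- function(regionParams,
                                       labeling = labelingCondition(),
                                       replicates = 3,
                                       noise = noiseModel(seed = 1),
                                       kInt = 1) {
  if (replicates < 1) stop("replicates must be >= 1")
  out <- list()
  for (rp in regionParams) {
    if (is.null(rp$peptide) || is.null(rp$pf) || is.null(rp$kOpen))
      stop("each region needs elements peptide, pf and kOpen")
    if (rp$pf < 1) stop("protection factor must be >= 1")
    if (rp$kOpen < 0) stop("kOpen must be >= 0")
    nat <- naturalEnvelope(peptideComposition(rp$peptide))
    nex <- peptideExchangeable(rp$peptide)
    openEnv <- applyDeuteration(nat, nex, labeling$d2oFraction)
    pepId <- sprintf("%s_%d_%d", rp$peptide@protein, rp$peptide@start,
                     rp$peptide@end)
    for (t in labeling$continuousTimes) {
      pClosed <- labeling$d2oFraction * (1 - exp(-kInt * t / rp$pf))
      w <- 1 - exp(-rp$kOpen * t)
      closedEnv <- applyDeuteration(nat, nex, pClosed)
      mixture <- mixEnvelopes(closedEnv, openEnv, w)
      for (r in seq_len(replicates)) {
        seed <- .deriveSeed(noise$seed, pepId, t * 1000, r)
        md <- list(time_s = t, pf = rp$pf, kOpen = rp$kOpen,
                   kInt = kInt, pClosed = pClosed, wOpen = w,
                   d2oFraction = labeling$d2oFraction, seed = seed)
        out[[length(out) + 1]] <-
          .makeSpectrum(.applyNoise(mixture, noise, seed), rp$peptide,
                        r, t / 60, pepId, md)
      }
    }
  }
  out
}

#' Region presets for the 159-residue ANGPTL4 coiled-coil domain
#'
#' A synthetic peptide map tiling the mature 1-159 sequence, with two
#' slow-exchanging helical regions (residues 19-43 and 85-111) and fast
#' exchange elsewhere. The `"e15k"` variant destabilizes the N-terminal
#' helix: peptides overlapping residues 19-43 open cooperatively (EX1)
#' about six-fold faster than in `"wt"`, so they take up more deuterium
#' at every labeling time. All parameters are declared modeling
#' choices, not measured values.
#'
#' @param variant `"wt"` or `"e15k"`.
#' @return list of region parameter lists for
#'   [simulateContinuousLabeling()].
#' @export
angptl4RegionPresets <- function(variant = c("wt", "e15k")) {
  variant <- match.arg(variant)
  tiles <- data.frame(
    start = c(1, 14, 19, 28, 40, 52, 66, 80, 85, 98, 110, 124, 138, 150),
    end = c(15, 27, 32, 43, 55, 68, 82, 95, 97, 111, 125, 139, 152, 159))
  helix1 <- c(19, 43); helix2 <- c(85, 111)
  kOpen1 <- if (variant == "wt") 5e-4 else 3e-3
  out <- vector("list", nrow(tiles))
  for (i in seq_len(nrow(tiles))) {
    s <- tiles$start[i]; e <- tiles$end[i]
    len <- e - s + 1
    pep <- PeptideSpec(paste0("ANGPTL4_", variant), s, e,
                       nExchangeable = as.integer(len - 2),
                       massDa = len * .AVERAGINE_MASS)
    inH1 <- s <= helix1[2] && e >= helix1[1]
    inH2 <- s <= helix2[2] && e >= helix2[1]
    out[[i]] <- if (inH1) list(peptide = pep, pf = 3000, kOpen = kOpen1)
    else if (inH2) list(peptide = pep, pf = 10000, kOpen = 0)
    else list(peptide = pep, pf = 20, kOpen = 0)
  }
  out
}

#' Write synthetic fixtures to disk
#'
#' Writes a spectra CSV (`preset, replicate, time_min, mass_da,
#' intensity`), a peptide table CSV and a JSON manifest recording the
#' seed, presets and generator parameters. Idempotent: the same seed
#' produces byte-identical files.
#'
#' @param dir output directory (created if needed).
#' @param presets character vector of empirical preset names (default:
#'   all empirical presets).
#' @param seed integer base seed.
#' @param replicates replicates per preset (default 3).
#' @param peptide the reporter peptide (default [diagnosticPeptide()]).
#' @return invisible list of written paths.
#' @export
writeFixtures <- function(dir,
                          presets = names(presetRegistry()$empirical),
                          seed, replicates = 3,
                          peptide = diagnosticPeptide()) {
  if (missing(seed)) stop("a seed is mandatory")
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", dir)
  rows <- list()
  for (nm in presets) {
    preset <- getPreset(nm)
    specs <- simulatePulseSpectra(preset, peptide = peptide,
                                  replicates = replicates,
                                  noise = noiseModel(seed = seed))
    for (sp in specs) {
      pk <- peaks(sp)
      rows[[length(rows) + 1]] <- data.frame(
        preset = sp@preset, replicate = sp@replicate,
        time_min = sp@timeMin, mass_da = round(pk$mass, 6),
        intensity = round(pk$abundance, 6))
    }
  }
  spectraPath <- file.path(dir, "spectra.csv")
  utils::write.csv(do.call(rbind, rows), spectraPath, row.names = FALSE,
                   quote = FALSE)
  peptidePath <- file.path(dir, "peptides.csv")
  writePeptideTable(list(peptide), peptidePath)
  manifestPath <- file.path(dir, "manifest.json")
  manifest <- list(seed = seed, replicates = replicates,
                   presets = lapply(presets, function(nm) {
                     p <- getPreset(nm)
                     list(name = nm, fraction = p$fraction,
                          time_min = p$timeMin, condition = p$condition)
                   }),
                   noise = list(cv = 0.03, baseline = 0.005),
                   package = "pulseHDX",
                   version = as.character(utils::packageVersion("pulseHDX")))
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(spectra = spectraPath, peptides = peptidePath,
                 manifest = manifestPath))
}
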